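# Geometry and bookkeeping of the 3-D cell lattice.
#
# Coordinate convention: 1-based (i, j, k) sites at 5 um pitch; x/y are
# periodic, z = 1 is the layer resting on the agarose surface and z
# increases upward. At most one cell per site; dead cells persist in place,
# occupy volume, block pushing, and count toward voxel occupancy.

#' Neighboring sites of a lattice position
#'
#' Returns in-bounds neighbor sites of `pos`, honoring the periodic x/y
#' wrap. `lateral8` gives the 8 sites at the same z; `full26` the 26-site
#' 3-D neighborhood (sites below z = 1 or above the ceiling are dropped, not
#' wrapped); `planar8` the 8 sites within the 2-D section spanned by the
#' first two coordinates.
#'
#' @param pos integer vector `c(i, j, k)` (or `c(i, j)` for `planar8`).
#' @param dim lattice extents, e.g. `dim(state$strain)`.
#' @param mode one of `"lateral8"`, `"full26"`, `"planar8"`.
#' @return integer matrix with one row per neighbor.
#' @export
neighbors <- function(pos, dim, mode = c("full26", "lateral8", "planar8")) {
  mode <- match.arg(mode)
  if (mode == "planar8") {
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
    off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
    out <- cbind((pos[1] - 1 + off[, 1]) %% dim[1] + 1,
                 (pos[2] - 1 + off[, 2]) %% dim[2] + 1)
    colnames(out) <- c("i", "j")
    return(out)
  }
  if (any(pos < 1) || any(pos > dim[seq_along(pos)]))
    abort("pos outside lattice")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1,
                               dz = if (mode == "lateral8") 0 else -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  k <- pos[3] + off[, 3]
  keep <- k >= 1 & k <= dim[3]  # out-of-domain z contributes nothing
  off <- off[keep, , drop = FALSE]
  out <- cbind((pos[1] - 1 + off[, 1]) %% dim[1] + 1,
               (pos[2] - 1 + off[, 2]) %% dim[2] + 1,
               pos[3] + off[, 3])
  colnames(out) <- c("i", "j", "k")
  out
}

#' Occupancy of community voxels
#'
#' Each 15 um community voxel covers a 3 x 3 x 3 block of cell sites and
#' maximally contains 27 cells; its occupancy fraction is the number of
#' cells present (live or dead) divided by 27.
#'
#' @param state a `sim_state`.
#' @return numeric array over the community grid with values in `[0, 1]`.
#' @export
occupancy_fraction <- function(state) {
  cpp_occupancy(state)
}

#' Cells as a tibble
#'
#' One row per cell with site coordinates, strain id, live flag, and the
#' accumulated stores of the required metabolite and glucose.
#'
#' @param state a `sim_state`.
#' @return a tibble.
#' @export
cells_tibble <- function(state) {
  idx <- which(state$strain != 0L)
  if (length(idx) == 0L)
    return(tibble(i = integer(), j = integer(), k = integer(),
                  strain = character(), alive = logical(),
                  store_req = numeric(), store_glc = numeric()))
  d <- dim(state$strain)
  coords <- arrayInd(idx, d)
  code <- state$strain[idx]
  tibble(i = coords[, 1], j = coords[, 2], k = coords[, 3],
         strain = state$strain_ids[abs(code)],
         alive = code > 0L,
         store_req = state$store_req[idx],
         store_glc = state$store_glc[idx])
}

# The support invariant: every cell above the bottom layer rests on an
# occupied site below it. The rearrangement rules only ever create supported
# cells; this asserts rather than enforces.
#' Check that no cell floats
#'
#' @param state a `sim_state`.
#' @return `TRUE` invisibly; aborts if a floating cell is found.
#' @export
assert_supported <- function(state) {
  s <- state$strain
  nz <- dim(s)[3]
  if (nz > 1L) {
    above <- s[, , 2:nz, drop = FALSE] != 0L
    below <- s[, , 1:(nz - 1), drop = FALSE] != 0L
    if (any(above & !below)) abort("support invariant violated: floating cell")
  }
  invisible(TRUE)
}
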