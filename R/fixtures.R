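# Tiny hand-checkable fixtures for tests and examples.

#' Hand-checkable fixture lattices
#'
#' Small label arrays with known association-index values, used throughout
#' the test suite and convenient for exploring the metrics:
#' \describe{
#'   \item{`"two_to_one"`}{a 5 x 5 plane where every qualifying cooperator
#'     has exactly two partner neighbors and every qualifying cheater
#'     exactly one, so the planar index is exactly 2.}
#'   \item{`"mirror"`}{a plane mirror-symmetric under swapping R and C, so
#'     the index is exactly 1.}
#'   \item{`"column_pair"`}{a 4 x 4 x 3 block with an R-G column pair and an
#'     isolated C column.}
#' }
#' Labels: 1 = R, 2 = G, 3 = C, 0 = empty.
#'
#' @param which fixture name.
#' @return an integer matrix or array.
#' @export
fixture_lattice <- function(which = c("two_to_one", "mirror", "column_pair")) {
  which <- match.arg(which)
  if (which == "two_to_one") {
    # R at (2,2) touches G at (1,1) and (3,3); C at (2,4) touches G at (3,3)
    m <- matrix(0L, 5, 5)
    m[1, 1] <- 2L
    m[3, 3] <- 2L
    m[2, 2] <- 1L
    m[2, 4] <- 3L
    return(m)
  }
  if (which == "mirror") {
    # columns: R G . G C -- swapping R and C maps the lattice onto its mirror
    m <- matrix(0L, 5, 5)
    m[, 1] <- 1L
    m[, 2] <- 2L
    m[, 4] <- 2L
    m[, 5] <- 3L
    return(m)
  }
  a <- array(0L, c(5, 5, 3))
  a[1, 1, ] <- 1L  # R column
  a[2, 2, ] <- 2L  # G column, diagonal neighbor of R
  a[4, 4, ] <- 3L  # C column, isolated even under the periodic wrap
  a
}

#' Desk-scale configuration presets
#'
#' Small, fast variants of the standard setups for examples and tests:
#' a reduced lateral domain with the full physical constants.
#'
#' @param domain_width lateral size (um), multiple of 60.
#' @param ... passed to [sim_config()].
#' @return a [sim_config()].
#' @export
mini_config <- function(domain_width = 180, ...) {
  sim_config(domain_width = domain_width, domain_height = 120,
             record_every_tau = 5L, ...)
}
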