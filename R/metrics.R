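# Quantification layer: partner association indexes, population ratios,
# fitness-advantage estimation, and center-vs-front region metrics.

# shift an array by (dx, dy[, dz]); x/y wrap optionally, z pads with 0
shift_labels <- function(a, dx, dy, dz = 0L, wrap = TRUE) {
  d <- dim(a)
  ix <- seq_len(d[1]) - dx
  iy <- seq_len(d[2]) - dy
  if (wrap) {
    ix <- (ix - 1L) %% d[1] + 1L
    iy <- (iy - 1L) %% d[2] + 1L
  }
  out <- array(if (is.character(a)) "" else 0L, d)
  okx <- ix >= 1L & ix <= d[1]
  oky <- iy >= 1L & iy <= d[2]
  if (length(d) == 2L) {
    out[okx, oky] <- a[ix[okx], iy[oky]]
    return(out)
  }
  iz <- seq_len(d[3]) - dz
  okz <- iz >= 1L & iz <= d[3]
  out[okx, oky, okz] <- a[ix[okx], iy[oky], iz[okz]]
  out
}

neighbor_offsets <- function(mode) {
  if (mode == "planar8") {
    off <- expand.grid(dx = -1:1, dy = -1:1, dz = 0L)
  } else if (mode == "planar4") {
    off <- data.frame(dx = c(1, -1, 0, 0), dy = c(0, 0, 1, -1), dz = 0L)
  } else if (mode == "full26") {
    off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  } else if (mode == "full6") {
    off <- data.frame(dx = c(1, -1, 0, 0, 0, 0), dy = c(0, 0, 1, -1, 0, 0),
                      dz = c(0, 0, 0, 0, 1, -1))
  } else abort("unknown neighborhood mode")
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), , drop = FALSE]
  off
}

#' Partner association index
#'
#' The ratio of the average number of partner neighbors per focal cell of
#' class `focal_a` to the average per focal cell of class `focal_b`,
#' counting only focal cells that neighbor at least one different
#' population. An index above 1 means class-a cells have more partner
#' neighbors than class-b cells.
#'
#' @param labels 2-D matrix or 3-D array of strain labels: 0 empty, positive
#'   codes live cells, negative codes dead cells; or a character array with
#'   `""`/`NA` empty. Dead cells are excluded from focal and neighbor counts
#'   by default.
#' @param focal_a,focal_b,partner label values (codes or strain ids) of the
#'   two focal classes and the partner class.
#' @param mode neighborhood connectivity: `"full26"` (default in 3-D),
#'   `"planar8"` (default in 2-D), or the stricter `"full6"` / `"planar4"`.
#' @param wrap treat x/y as periodic (lattice sections); use `FALSE` for
#'   image-derived label rasters.
#' @param include_dead count dead cells as members of their population.
#' @return an `assoc_result`: list with `index`, `mean_a`, `mean_b`,
#'   `n_focal_a`, `n_focal_b`, `mode`, and `status` (`"ok"` or
#'   `"undefined"` when either focal class has no qualifying cells).
#' @export
association_index <- function(labels, focal_a = "R", focal_b = "C",
                              partner = "G", mode = NULL, wrap = TRUE,
                              include_dead = FALSE) {
  d <- dim(labels)
  if (is.null(d)) abort("labels must be a matrix or 3-D array")
  mode <- mode %||% if (length(d) == 2L) "planar8" else "full26"
  if (length(d) == 3L && !is.character(labels)) {
    # trim empty sky: keep layers up to the highest occupied one
    occ_k <- which(apply(labels != 0L, 3, any))
    if (length(occ_k) && max(occ_k) < d[3]) {
      labels <- labels[, , seq_len(max(occ_k)), drop = FALSE]
      d <- dim(labels)
    }
  }
  if (is.character(labels)) {
    labels[is.na(labels) | labels == ""] <- ""
    codes <- labels
    lab_of <- function(x) codes == x
  } else {
    if (!include_dead) labels[labels < 0L] <- 0L else labels <- abs(labels)
    lab_of <- function(x) labels == x
  }
  if (is.character(labels) && !include_dead) {
    # character arrays carry no dead encoding; caller pre-filters
  }
  occupied <- if (is.character(labels)) labels != "" else labels != 0L
  is_a <- lab_of(focal_a); is_b <- lab_of(focal_b); is_p <- lab_of(partner)

  off <- neighbor_offsets(mode)
  pn <- array(0L, d)       # partner neighbors
  diffn <- array(0L, d)    # different-population neighbors
  for (r in seq_len(nrow(off))) {
    sp <- shift_labels(is_p * 1L, off$dx[r], off$dy[r], off$dz[r], wrap)
    so <- shift_labels(occupied * 1L, off$dx[r], off$dy[r], off$dz[r], wrap)
    ss <- if (is.character(labels))
      shift_labels(labels, off$dx[r], off$dy[r], off$dz[r], wrap)
    else
      shift_labels(labels, off$dx[r], off$dy[r], off$dz[r], wrap)
    pn <- pn + sp
    same <- if (is.character(labels)) ss == labels else ss == labels
    diffn <- diffn + (so == 1L) * (!same)
  }
  qa <- is_a & diffn > 0L
  qb <- is_b & diffn > 0L
  na <- sum(qa); nb <- sum(qb)
  if (na == 0L || nb == 0L) {
    return(structure(list(index = NA_real_, mean_a = NA_real_,
                          mean_b = NA_real_, n_focal_a = na, n_focal_b = nb,
                          mode = mode, status = "undefined"),
                     class = "assoc_result"))
  }
  ma <- mean(pn[qa]); mb <- mean(pn[qb])
  idx <- if (mb == 0) {
    if (ma == 0) NA_real_ else Inf
  } else ma / mb
  structure(list(index = idx, mean_a = ma, mean_b = mb,
                 n_focal_a = na, n_focal_b = nb, mode = mode,
                 status = if (is.na(idx)) "undefined" else "ok"),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("<assoc_result> index = ", signif(x$index, 4), " (", x$mode, "; ",
      x$n_focal_a, " vs ", x$n_focal_b, " qualifying focal cells; ",
      x$status, ")\n", sep = "")
  invisible(x)
}

#' 3-D association index along a trajectory
#'
#' Computes the full-26-neighborhood association index over the whole
#' community for every stored snapshot. For random initial lawns the series
#' starts at approximately 1 and, under cooperation and cheating, rises to a
#' steady level above 1.
#'
#' @param traj a `trajectory` from [run_spatial()].
#' @inheritParams association_index
#' @return a tibble with `time_hr`, `generation`, `index`, `status` and
#'   focal counts; also cached on the trajectory as `traj$assoc`.
#' @export
association_index_3d_timeseries <- function(traj, focal_a = "R",
                                            focal_b = "C", partner = "G",
                                            mode = "full26") {
  stopifnot(inherits(traj, "trajectory"))
  ids <- traj$snapshots[[1]]$strain_ids
  code <- function(x) {
    m <- match(x, ids)
    if (is.na(m)) abort(paste0("unknown strain id: ", x))
    m
  }
  rows <- lapply(traj$snapshots, function(sn) {
    a <- association_index(sn$strain, code(focal_a), code(focal_b),
                           code(partner), mode = mode, wrap = TRUE)
    tibble(time_hr = sn$time_hr, generation = sn$generation,
           index = a$index, mean_a = a$mean_a, mean_b = a$mean_b,
           n_focal_a = a$n_focal_a, n_focal_b = a$n_focal_b,
           status = a$status)
  })
  bind_rows(rows)
}

#' Live-cell population ratio
#'
#' @param state a `sim_state` or a `trajectory` (final state).
#' @param a,b strain ids.
#' @return live count of `a` divided by live count of `b`; `Inf` with a
#'   warning if `b` is extinct.
#' @export
population_ratio <- function(state, a = "R", b = "C") {
  if (inherits(state, "trajectory")) state <- state$state
  cc <- strain_counts(state)
  la <- cc$live[match(a, cc$strain)]
  lb <- cc$live[match(b, cc$strain)]
  if (is.na(la) || is.na(lb)) abort("unknown strain id")
  if (lb == 0L) {
    warning("strain '", b, "' extinct: ratio infinite")
    return(Inf)
  }
  la / lb
}

#' Per-generation fitness advantage from a ratio series
#'
#' Least-squares slope of `ln(ratio)` against generations over the window,
#' exponentiated minus one, times 100: the percent change of the ratio per
#' community generation. Positive values favor the numerator strain.
#'
#' @param series a tibble/data.frame with columns `generation` and `ratio`.
#' @param g_start,g_end generation window (default 2 to 6).
#' @return percent per generation (scalar).
#' @export
fitness_advantage <- function(series, g_start = 2, g_end = 6) {
  s <- series[series$generation >= g_start - 1e-9 &
              series$generation <= g_end + 1e-9, ]
  s <- s[is.finite(s$ratio) & s$ratio > 0, ]
  if (nrow(s) < 2L ||
      min(s$generation) > g_start + 0.5 || max(s$generation) < g_end - 0.5)
    abort(sprintf("ratio series does not cover generations [%g, %g]",
                  g_start, g_end))
  slope <- unname(coef(lm(log(ratio) ~ generation, data = s))[2])
  (exp(slope) - 1) * 100
}

#' Ratio time series from a trajectory
#'
#' @param traj a `trajectory`.
#' @param a,b strain ids.
#' @return tibble with `time_hr`, `generation`, `ratio`.
#' @export
ratio_series <- function(traj, a = "R", b = "C") {
  s <- traj$series
  ca <- s[[paste0("live_", a)]]
  cb <- s[[paste0("live_", b)]]
  tibble(time_hr = s$time_hr, generation = s$generation, ratio = ca / cb)
}

#' Center versus expanding-front metrics
#'
#' For spot-initiated range expansions, classifies lattice columns as
#' "center" (inside the initial inoculum footprint) or "front" (outside)
#' and reports live counts, the focal ratio, and the association index per
#' region.
#'
#' @param state a `sim_state` initialized with [init_spot()] (or a
#'   `trajectory` thereof).
#' @param a,b,partner strain ids.
#' @return a tibble with one row per region: `region`, per-strain live
#'   counts, `ratio` (a:b), `assoc_index`, `assoc_status`.
#' @export
region_split_metrics <- function(state, a = "R", b = "C", partner = "G") {
  if (inherits(state, "trajectory")) state <- state$state
  fp <- state$inoculum_footprint
  if (is.null(fp)) abort("state has no inoculum footprint (not a spot protocol)")
  d <- dim(state$strain)
  mask3 <- array(fp, d)  # recycles over z, column-classified
  code <- function(x) strain_code_of(state, x)
  one_region <- function(sel) {
    lab <- state$strain
    lab[!sel] <- 0L
    live <- tabulate(lab[lab > 0L], nbins = length(state$strain_ids))
    names(live) <- state$strain_ids
    ai <- association_index(lab, code(a), code(b), code(partner),
                            mode = "full26", wrap = TRUE)
    ratio <- if (live[[b]] > 0) live[[a]] / live[[b]] else
      if (live[[a]] > 0) Inf else NA_real_
    row <- tibble(ratio = ratio, assoc_index = ai$index,
                  assoc_status = ai$status, n_live = sum(live))
    for (id in state$strain_ids) row[[paste0("live_", id)]] <- live[[id]]
    row
  }
  center <- one_region(mask3)
  front <- one_region(!mask3)
  out <- bind_rows(center, front)
  out$region <- c("center", "front")
  dplyr::relocate(out, "region")
}
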