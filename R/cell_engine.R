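# Per-tau cell updates: quota accumulation, division with rearrangement,
# stochastic death with release. All randomness draws from the session RNG,
# so a single set.seed() makes whole trajectories bit-reproducible.

#' Metabolite uptake of a single cell over one window
#'
#' Reference implementation of the per-cell uptake rule: a cell whose quota
#' is already met consumes nothing; otherwise the amount consumed over a
#' window `t_u` is `min(v_m S / (S + K) * t_u, share)` where `share` is the
#' cell's proportional share of the mass available in its voxel. The
#' stop-consuming check is applied at window granularity, so the final
#' window before quota completion may overshoot by at most `v_m t_u`; the
#' overshoot carries over after division, keeping division timing
#' continuous in time rather than quantized to the cell-update interval
#' (a sub-tau rate advantage would otherwise never express). This R-level
#' function mirrors the engine's inner loop and is used as its cross-check.
#'
#' @param vm maximum uptake rate (fmole/hr).
#' @param K half-saturation concentration (fmole/um^3).
#' @param S local concentration (fmole/um^3).
#' @param store current store (fmole).
#' @param quota division quota (fmole).
#' @param t_u window length in hours.
#' @param available mass available to this cell in its voxel (fmole);
#'   defaults to unlimited.
#' @return amount consumed (fmole).
#' @export
uptake_window <- function(vm, K, S, store, quota, t_u, available = Inf) {
  if (S < 0) abort("negative concentration")
  if (store >= quota - 1e-9) return(0)
  min(vm * S / (S + K) * t_u, available)
}

#' Stochastic death step
#'
#' Each live cell dies independently with probability `death_rate * tau`.
#' Dying cells are flagged dead but retained in place (they keep occupying
#' volume and blocking rearrangement). The on-death release of dying cells
#' (beta_L lysine for partner-type strains) is deposited into a per-voxel
#' source map consumed by the next [step_fields()] window.
#'
#' @param state a `sim_state` (modified in place).
#' @return tibble of deaths per strain, invisibly accumulated in
#'   `state$deaths`.
#' @export
death_step <- function(state) {
  d <- cpp_death_step(state)
  state$deaths <- state$deaths + as.integer(d)
  invisible(tibble(strain = state$strain_ids, deaths = as.integer(d)))
}

#' Division step
#'
#' Every live cell that has acquired both its required-metabolite quota and
#' its glucose quota divides exactly once this window (iteration order
#' randomized). The mother's stores drop by one quota per metabolite
#' (leftovers carry over); the daughter starts with empty stores and is
#' placed by the rearrangement rule (see [place_daughter()]).
#'
#' @param state a `sim_state` (modified in place).
#' @return a tibble of division events (`mother`, `daughter`, `n_pushed`,
#'   `mode`), with sites as linear lattice indices.
#' @export
attempt_divisions <- function(state) {
  res <- cpp_attempt_divisions(state)
  state$births <- state$births + as.integer(res$births)
  as_tibble(res$events)
}

#' Daughter placement and cell rearrangement
#'
#' If an empty lateral site exists within the enclosure radius (default 5
#' cells, "roughly five cells") along one of the 8 lateral rays from the
#' mother, the daughter is placed adjacent along a shortest such ray and the
#' intervening chain of cells shifts one site outward (ties between
#' equidistant rays broken uniformly at random). Otherwise the mother is
#' enclosed: with probability 0.7 the daughter takes the site directly above
#' the mother, displacing the vertical column upward; with probability 0.3 a
#' uniformly chosen lateral neighbor is displaced upward together with all
#' cells above it and the daughter takes its site.
#'
#' @param state a `sim_state` (modified in place).
#' @param mother `c(i, j, k)` site of a live cell.
#' @return a list with `daughter` (site index `c(i, j, k)`), `chain`
#'   (matrix of pushed sites, pre-push positions), and `mode`
#'   (`"lateral"`, `"up"`, or `"side_up"`).
#' @export
place_daughter <- function(state, mother) {
  d <- dim(state$strain)
  idx0 <- (mother[1] - 1) + d[1] * ((mother[2] - 1) + d[2] * (mother[3] - 1))
  res <- cpp_place_daughter(state, as.integer(idx0))
  list(daughter = as.integer(arrayInd(res$daughter, d)),
       chain = arrayInd(res$chain, d),
       mode = c("lateral", "up", "side_up")[res$mode + 1])
}

#' Advance one tau window
#'
#' The per-tau update: stochastic deaths (whose release sources the window),
#' all diffusion/uptake/release t_u steps of the window, divisions with
#' rearrangement, then the occupancy-proportional diffusivity update.
#'
#' @param state a `sim_state` (modified in place).
#' @return a list with `deaths` and `births` tibbles for the window.
#' @export
tau_step <- function(state) {
  deaths <- death_step(state)
  step_fields(state)
  events <- attempt_divisions(state)
  update_D(state)
  state$time_hr <- state$time_hr + state$par$tau_hr
  state$tau_count <- state$tau_count + 1L
  invisible(list(deaths = deaths, events = events))
}
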