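# Reaction-diffusion of adenine, lysine, and glucose on the dual-resolution
# grid. The finite-difference update follows the standard explicit scheme
# with a spatially varying D (harmonic face averaging), no-flow boundaries
# at the top of the community domain and the bottom of the agarose, periodic
# lateral boundaries, and flux-conservative exchange between each 60 um
# agarose interface voxel and its 4 x 4 overlying 15 um community voxels.
# Because the printed t_u violates the explicit 3-D stability bound
# (D t_u / h^2 = 0.35 > 1/6 on the agarose grid), every t_u is sub-stepped
# internally; sources and sinks are applied once per t_u as in the printed
# update.

#' Advance the metabolite fields
#'
#' Runs `n_tu` physical diffusion steps of t_u: Michaelis-Menten uptake by
#' live cells (clamped so no voxel goes negative and no cell exceeds its
#' remaining quota; within-voxel shortfalls are split among requesting cells
#' proportionally to their unclamped demands), continuous release
#' (gamma_A-type terms), this window's death release (beta_L mass deposited
#' by [death_step()], spread evenly over the window), then diffusion.
#' Cumulative release/consumption ledgers are updated. With the
#' `instant_distribution` flag each field is additionally replaced by its
#' volume-weighted spatial mean after every step.
#'
#' @param state a `sim_state` (modified in place).
#' @param n_tu number of t_u steps; defaults to one full tau window.
#' @return the state, invisibly.
#' @export
step_fields <- function(state, n_tu = state$par$n_tu) {
  cpp_step_fields(state, as.integer(n_tu))
  invisible(state)
}

#' One instantly-distributed field step
#'
#' Convenience wrapper: a single t_u with the instant-distribution variant
#' forced on (identical sinks and sources, but every field is spatially
#' uniform afterwards).
#'
#' @inheritParams step_fields
#' @return the state, invisibly.
#' @export
instant_distribution_step <- function(state, n_tu = 1L) {
  old <- state$par$instant
  state$par$instant <- 1L
  on.exit(state$par$instant <- old)
  cpp_step_fields(state, as.integer(n_tu))
  invisible(state)
}

#' Update the spatially varying diffusion coefficient
#'
#' The diffusion coefficient of each community voxel is proportional to its
#' occupancy (live or dead cells out of 27), ranging from 0 (air) to the
#' community maximum; agarose voxels keep the agarose coefficient. Called
#' after every cell state update.
#'
#' @param state a `sim_state` (modified in place).
#' @return the state, invisibly.
#' @export
update_D <- function(state) {
  cpp_update_D(state)
  invisible(state)
}

#' Total mass of a metabolite over both grids
#'
#' Sums concentration times voxel volume over the community/air and agarose
#' grids, plus (optionally) the amounts stored inside cells.
#'
#' @param state a `sim_state`.
#' @param metabolite `"adenine"`, `"lysine"`, or `"glucose"`.
#' @param include_stores if `TRUE`, add cell-internal stores.
#' @return total mass in fmole.
#' @export
total_mass <- function(state, metabolite = c("adenine", "lysine", "glucose"),
                       include_stores = FALSE) {
  metabolite <- match.arg(metabolite)
  f <- switch(metabolite,
              adenine = list(state$SA_c, state$SA_a),
              lysine = list(state$SL_c, state$SL_a),
              glucose = list(state$SG_c, state$SG_a))
  m <- sum(f[[1]]) * state$geo$Vc + sum(f[[2]]) * state$geo$Va
  if (include_stores) {
    code <- abs(state$strain)
    occ <- code != 0L
    if (metabolite == "glucose") {
      m <- m + sum(state$store_glc[occ])
    } else {
      want_A <- metabolite == "adenine"
      is_A <- state$par$req_is_A[code[occ]] == 1L
      m <- m + sum(state$store_req[occ][is_A == want_A])
    }
  }
  m
}

#' Mass ledgers
#'
#' Cumulative released and consumed mass per metabolite since
#' initialization. The solver maintains the identity
#' `delta total_mass = released - consumed` to solver tolerance.
#'
#' @param state a `sim_state`.
#' @return a tibble with columns `metabolite`, `released`, `consumed`.
#' @export
mass_ledger <- function(state) {
  tibble(metabolite = c("adenine", "lysine", "glucose"),
         released = as.numeric(state$led_rel),
         consumed = as.numeric(state$led_con))
}
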