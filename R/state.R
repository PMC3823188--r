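# SimulationState: lattice + fields + clock + ledgers, held in an
# environment so the Rcpp engine can update it in place (reference
# semantics, like an R6 object). Use copy_state() for an independent copy.

#' Create a simulation state
#'
#' Allocates the 3-D cell lattice (5 um sites; strain codes, with dead cells
#' carried as negative codes) and the dual-resolution metabolite fields
#' (adenine, lysine, glucose on the 15 um community/air grid and the 60 um
#' agarose grid), places the medium's supplements and glucose in the
#' agarose, and precomputes the per-strain kinetic vectors used by the
#' engine. The state has reference semantics: engine steps modify it in
#' place.
#'
#' @param config a [sim_config()].
#' @param medium a [medium_spec()].
#' @param strains list of [strain_spec()]; strain codes follow list order.
#' @return an environment of class `sim_state`.
#' @export
simulation_state <- function(config, medium, strains) {
  stopifnot(inherits(config, "sim_config"), inherits(medium, "medium_spec"))
  pitch <- config$cell_pitch
  nx <- config$domain_width / pitch
  ny <- nx
  nz <- config$domain_height / pitch
  rat_c <- config$community_grid / pitch               # 3
  rat_a <- config$agarose_grid / config$community_grid # 4
  if (nz %% rat_c != 0)
    abort("invalid-config: domain_height must hold whole community voxels")
  ncx <- nx / rat_c; ncy <- ny / rat_c; ncz <- nz / rat_c
  nax <- ncx / rat_a; nay <- ncy / rat_a
  naz <- medium$agarose_height / config$agarose_grid
  if (naz != round(naz))
    abort("invalid-config: agarose_height must be a multiple of agarose_grid")
  naz <- as.integer(naz)

  geo <- list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
              ncx = as.integer(ncx), ncy = as.integer(ncy), ncz = as.integer(ncz),
              nax = as.integer(nax), nay = as.integer(nay), naz = naz,
              hc = config$community_grid, ha = config$agarose_grid,
              Vc = config$community_grid^3, Va = config$agarose_grid^3,
              pitch = pitch)

  ids <- unname(vapply(strains, function(s) s$id, character(1)))
  if (anyDuplicated(ids)) abort("invalid-spec: duplicate strain ids")

  D_max_hr <- (if (config$uniform_D) config$D_agarose else config$D_community_max) * 3600
  D_ag_hr <- config$D_agarose * 3600
  tu_hr <- config$diffusion_timestep_tu / 3600
  tau_hr <- config$cell_update_interval_tau / 60
  n_tu <- max(1L, as.integer(round(tau_hr / tu_hr)))
  dt_max <- min(geo$hc^2 / (6 * max(D_max_hr, 1e-12)),
                geo$ha^2 / (6 * D_ag_hr))
  n_sub <- max(1L, as.integer(ceiling(tu_hr / dt_max)))

  num <- function(f) vapply(strains, function(s) as.numeric(f(s)), numeric(1))
  relA <- num(function(s) {
    if (s$release_mode == "continuous" && s$required_metabolite == "lysine")
      s$release_rate_gamma * s$release_fraction_d * config$excess_release_factor
    else 0
  })
  relL <- num(function(s) {
    if (s$release_mode == "continuous" && s$required_metabolite == "adenine")
      s$release_rate_gamma * s$release_fraction_d * config$excess_release_factor
    else 0
  })
  relDA <- num(function(s) {
    if (s$release_mode == "on_death" && s$required_metabolite == "lysine")
      s$release_on_death_beta * config$excess_release_factor else 0
  })
  relDL <- num(function(s) {
    if (s$release_mode == "on_death" && s$required_metabolite == "adenine")
      s$release_on_death_beta * config$excess_release_factor else 0
  })

  par <- list(
    vm_req = num(derive_vm),
    K_req = num(function(s) uM_to_conc(s$monod_K)),
    quota_req = num(function(s) s$quota_alpha),
    req_is_A = as.integer(num(function(s) s$required_metabolite == "adenine")),
    vm_glc = num(function(s) s$fitness_multiplier * s$glucose_quota * s$r_max / log(2)),
    K_glc = rep(uM_to_conc(config$glucose_monod_K), length(strains)),
    quota_glc = num(function(s) s$glucose_quota),
    rel_cont_A = relA, rel_cont_L = relL,
    rel_death_A = relDA, rel_death_L = relDL,
    death_rate = num(function(s) s$death_rate),
    tu_hr = tu_hr, tau_hr = tau_hr, n_tu = n_tu, n_sub = n_sub,
    D_ag_hr = D_ag_hr, D_max_hr = D_max_hr,
    p_up = config$vertical_bud_probability,
    enclosure_radius = as.integer(config$enclosure_radius_cells),
    instant = as.integer(isTRUE(config$instant_distribution)))

  st <- new.env(parent = emptyenv())
  st$geo <- geo
  st$par <- par
  st$cfg <- config
  st$medium <- medium
  st$strains <- strains
  st$strain_ids <- ids
  st$strain <- array(0L, c(nx, ny, nz))
  st$store_req <- array(0, c(nx, ny, nz))
  st$store_glc <- array(0, c(nx, ny, nz))
  dimc <- c(ncx, ncy, ncz)
  dima <- c(nax, nay, naz)
  st$SA_c <- array(0, dimc); st$SL_c <- array(0, dimc); st$SG_c <- array(0, dimc)
  st$SA_a <- array(uM_to_conc(medium$supplemented_adenine), dima)
  st$SL_a <- array(uM_to_conc(medium$supplemented_lysine), dima)
  st$SG_a <- array(uM_to_conc(medium$initial_glucose), dima)
  st$D_c <- array(0, dimc)
  st$death_src_A <- array(0, dimc)
  st$death_src_L <- array(0, dimc)
  st$led_rel <- c(A = 0, L = 0, G = 0)
  st$led_con <- c(A = 0, L = 0, G = 0)
  st$time_hr <- 0
  st$tau_count <- 0L
  st$zmax <- 1L  # highest occupied layer (engine scans stop here)
  st$births <- setNames(integer(length(strains)), ids)
  st$deaths <- setNames(integer(length(strains)), ids)
  st$initial_live <- 0L
  st$status <- "initialized"
  class(st) <- c("sim_state", "environment")
  st
}

#' @export
print.sim_state <- function(x, ...) {
  cc <- strain_counts(x)
  cat("<sim_state> t = ", round(x$time_hr, 2), " hr, ",
      sum(cc$live), " live / ", sum(cc$dead), " dead cells (",
      paste(sprintf("%s:%d", cc$strain, cc$live), collapse = " "),
      "), status: ", x$status, "\n", sep = "")
  invisible(x)
}

#' Deep-copy a simulation state
#'
#' States are environments (reference semantics); this returns an
#' independent copy.
#'
#' @param state a `sim_state`.
#' @return a new `sim_state`.
#' @export
copy_state <- function(state) {
  st <- new.env(parent = emptyenv())
  for (nm in ls(state, all.names = TRUE)) {
    v <- get(nm, envir = state)
    # force-copy numeric/integer payloads: the engine mutates them in place
    if (is.integer(v)) v <- v + 0L else if (is.double(v)) v <- v + 0
    assign(nm, v, envir = st)
  }
  class(st) <- class(state)
  st
}

#' Live/dead cell counts per strain
#'
#' @param state a `sim_state`.
#' @return a tibble with columns `strain`, `live`, `dead`.
#' @export
strain_counts <- function(state) {
  n <- length(state$strain_ids)
  s <- state$strain
  live <- tabulate(s[s > 0L], nbins = n)
  dead <- tabulate(-s[s < 0L], nbins = n)
  tibble(strain = state$strain_ids, live = live, dead = dead)
}

#' Number of community generations elapsed
#'
#' Generations are counted as log2 of the live-cell fold change since
#' initialization.
#'
#' @param state a `sim_state`.
#' @return numeric scalar.
#' @export
generations <- function(state) {
  live <- sum(state$strain > 0L)
  if (state$initial_live == 0L) return(0)
  log2(live / state$initial_live)
}

# Place cells on the lattice at given 1-based site coordinates. Initial
# stores are drawn uniformly on [0, quota) per metabolite (seeded via the
# session RNG), mirroring "random initial storage".
place_cells <- function(state, x, y, z, strain_code) {
  stopifnot(length(x) == length(y), length(x) == length(z),
            length(strain_code) == length(x))
  idx <- cbind(x, y, z)
  if (any(state$strain[idx] != 0L)) abort("site already occupied")
  state$strain[idx] <- as.integer(strain_code)
  qr <- state$par$quota_req[strain_code]
  qg <- state$par$quota_glc[strain_code]
  state$store_req[idx] <- runif(length(x)) * qr
  state$store_glc[idx] <- runif(length(x)) * qg
  state$zmax <- max(state$zmax, min(max(z) + 1L, dim(state$strain)[3]))
  state$initial_live <- sum(state$strain > 0L)
  update_D(state)
  invisible(state)
}

strain_code_of <- function(state, id) {
  m <- match(id, state$strain_ids)
  if (anyNA(m)) abort(paste0("unknown strain id: ", paste(id[is.na(m)], collapse = ", ")))
  m
}
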