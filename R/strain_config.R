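# Strain, medium, and simulation configuration.
#
# Paper-printed constants (grid sizes, diffusion coefficients, t_u, tau,
# upward-budding probability, supplement concentrations, densities) carry
# their literature values as defaults. Kinetic constants that the source
# publication defers to its supplementary data file (r_max, Monod constants,
# quotas, release rates, death rates, initial glucose) are ASSUMED defaults,
# chosen once to give a ~2 hr minimum doubling time and visible community
# growth within <= 8 generations; see the methods vignette.

#' Define a strain
#'
#' A strain is described by its division quotas, Michaelis-Menten uptake
#' kinetics for its required metabolite, its release behavior for the
#' metabolite it overproduces, and its stochastic death rate. The metabolite
#' a strain releases is always the one it does not require (adenine for
#' lysine-requiring strains, lysine for adenine-requiring strains).
#'
#' @param id short strain name, e.g. `"R"`, `"G"`, `"C"`.
#' @param required_metabolite `"lysine"` or `"adenine"`.
#' @param quota_alpha amount (fmole) of the required metabolite needed per
#'   division (the quota alpha_L or alpha_A).
#' @param glucose_quota amount (fmole) of the shared resource needed per
#'   division (alpha_G).
#' @param r_max maximum growth rate (per hr).
#' @param monod_K half-saturation (Monod) concentration of the required
#'   metabolite, in uM.
#' @param fitness_multiplier dimensionless scaling of maximum uptake;
#'   1.02 programs a 2% intrinsic fitness advantage.
#' @param release_mode `"continuous"`, `"on_death"`, or `"none"`.
#' @param release_rate_gamma continuous release rate (fmole per live cell per
#'   hr) of the non-required metabolite; gamma_A for adenine releasers.
#' @param release_on_death_beta amount (fmole) released when a cell dies;
#'   beta_L for lysine releasers.
#' @param release_fraction_d dimensionless factor in `[0, 1]` scaling
#'   continuous release; partial releasers produce at a d-fold rate.
#' @param death_rate stochastic death rate (per hr).
#' @return a `strain_spec` object (a named list).
#' @examples
#' strain_spec("R", "lysine", quota_alpha = 2, r_max = 0.35,
#'             release_mode = "continuous", release_rate_gamma = 0.4)
#' @export
strain_spec <- function(id,
                        required_metabolite = c("lysine", "adenine"),
                        quota_alpha = 2,
                        glucose_quota = 8,
                        r_max = 0.35,
                        monod_K = 1,
                        fitness_multiplier = 1,
                        release_mode = c("none", "continuous", "on_death"),
                        release_rate_gamma = 0,
                        release_on_death_beta = 0,
                        release_fraction_d = 1,
                        death_rate = 0.015) {
  required_metabolite <- match.arg(required_metabolite)
  release_mode <- match.arg(release_mode)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort("invalid-spec: `id` must be a non-empty string")
  if (quota_alpha <= 0 || glucose_quota <= 0)
    abort("invalid-spec: quotas must be positive")
  if (r_max <= 0) abort("invalid-spec: `r_max` must be positive")
  if (monod_K <= 0) abort("invalid-spec: `monod_K` must be positive")
  if (fitness_multiplier <= 0)
    abort("invalid-spec: `fitness_multiplier` must be positive")
  if (release_fraction_d < 0 || release_fraction_d > 1)
    abort("invalid-spec: `release_fraction_d` must lie in [0, 1]")
  if (death_rate < 0) abort("invalid-spec: `death_rate` must be >= 0")
  if (release_mode == "none" &&
      (release_rate_gamma != 0 || release_on_death_beta != 0))
    abort("invalid-spec: release_mode 'none' requires gamma = beta = 0")
  structure(
    list(id = id,
         required_metabolite = required_metabolite,
         quota_alpha = quota_alpha,
         glucose_quota = glucose_quota,
         r_max = r_max,
         monod_K = monod_K,
         fitness_multiplier = fitness_multiplier,
         release_mode = release_mode,
         release_rate_gamma = release_rate_gamma,
         release_on_death_beta = release_on_death_beta,
         release_fraction_d = release_fraction_d,
         death_rate = death_rate),
    class = "strain_spec")
}

#' @export
print.strain_spec <- function(x, ...) {
  cat("<strain_spec> ", x$id, ": requires ", x$required_metabolite,
      " (alpha = ", x$quota_alpha, " fmole, K = ", x$monod_K, " uM), ",
      "r_max = ", x$r_max, "/hr x ", x$fitness_multiplier,
      ", release = ", x$release_mode, "\n", sep = "")
  invisible(x)
}

#' Maximum uptake rate from growth parameters
#'
#' The maximum per-cell uptake rate of the limiting metabolite follows from
#' the division quota and the maximum growth rate as
#' `v_m = fitness_multiplier * quota_alpha * r_max / ln 2`
#' (fmole per cell per hr): at saturating concentrations a cell gathers one
#' quota per minimum doubling time ln2 / r_max.
#'
#' @param spec a [strain_spec()].
#' @return maximum uptake rate in fmole/hr/cell.
#' @examples
#' derive_vm(strain_spec("R", "lysine", quota_alpha = 2, r_max = log(2)))  # 2
#' @export
derive_vm <- function(spec) {
  stopifnot(inherits(spec, "strain_spec"))
  if (spec$quota_alpha <= 0 || spec$r_max <= 0)
    abort("invalid-spec: quota and r_max must be positive")
  spec$fitness_multiplier * spec$quota_alpha * spec$r_max / log(2)
}

#' The standard three-strain panel
#'
#' Builds the canonical community: a cooperator `R` that requires lysine and
#' continuously releases adenine; a partner `G` that requires adenine and
#' releases lysine upon death; and a third lysine-requiring strain that
#' releases adenine at a `d`-fold rate of the cooperator's and carries an
#' intrinsic fitness advantage. With `release_fraction_d = 0` the third
#' strain is the non-releasing cheater `C`; with `0 < d < 1` it is the
#' partial releaser `Rd`; with `d = 1` and zero advantage it is a clone of
#' `R`.
#'
#' @param cheater_advantage intrinsic fitness advantage of the third strain
#'   as a fraction (0.02 programs a 2% advantage, i.e. fitness multiplier
#'   1.02).
#' @param release_fraction_d adenine release of the third strain relative to
#'   the cooperator's rate.
#' @param base optional named list overriding the ASSUMED kinetic defaults
#'   shared by the strains (`quota_alpha_L`, `quota_alpha_A`,
#'   `glucose_quota`, `r_max`, `monod_K_L`, `monod_K_A`, `gamma_A`,
#'   `beta_L`, `death_rate_R`, `death_rate_G`, `death_rate_C`).
#' @return a named list of three [strain_spec()] objects (`R`, `G`, and `C`
#'   or `Rd`).
#' @export
default_panel <- function(cheater_advantage = 0.02,
                          release_fraction_d = 0,
                          base = list()) {
  if (cheater_advantage < 0)
    abort("invalid-spec: `cheater_advantage` must be >= 0")
  b <- modifyList(list(
    quota_alpha_L = 4, quota_alpha_A = 1, glucose_quota = 8,
    r_max = 0.35, monod_K_L = 50, monod_K_A = 0.5,
    gamma_A = 0.4, beta_L = 24,
    death_rate_R = 0.015, death_rate_G = 0.05, death_rate_C = 0.015),
    base)
  R <- strain_spec("R", "lysine",
                   quota_alpha = b$quota_alpha_L,
                   glucose_quota = b$glucose_quota,
                   r_max = b$r_max, monod_K = b$monod_K_L,
                   release_mode = "continuous",
                   release_rate_gamma = b$gamma_A,
                   death_rate = b$death_rate_R)
  G <- strain_spec("G", "adenine",
                   quota_alpha = b$quota_alpha_A,
                   glucose_quota = b$glucose_quota,
                   r_max = b$r_max, monod_K = b$monod_K_A,
                   release_mode = "on_death",
                   release_on_death_beta = b$beta_L,
                   death_rate = b$death_rate_G)
  third_id <- if (release_fraction_d == 0) "C" else "Rd"
  third <- strain_spec(third_id, "lysine",
                       quota_alpha = b$quota_alpha_L,
                       glucose_quota = b$glucose_quota,
                       r_max = b$r_max, monod_K = b$monod_K_L,
                       fitness_multiplier = 1 + cheater_advantage,
                       release_mode = if (release_fraction_d > 0) "continuous" else "none",
                       release_rate_gamma = if (release_fraction_d > 0) b$gamma_A else 0,
                       release_fraction_d = release_fraction_d,
                       death_rate = b$death_rate_C)
  stats::setNames(list(R, G, third), c("R", "G", third_id))
}

#' Define the growth medium
#'
#' The agarose column initially carries the shared resource (glucose) and,
#' for competition experiments, lysine and adenine supplements at the
#' standard 650 uM / 430 uM final concentrations.
#'
#' @param supplemented_lysine lysine concentration in the agarose (uM).
#' @param supplemented_adenine adenine concentration in the agarose (uM).
#' @param initial_glucose glucose concentration in the agarose (uM); ASSUMED
#'   default 110000 uM (110 mM, ~2% w/v) keeps the shared resource
#'   non-limiting at desk scale.
#' @param agarose_height agarose column height (um); ASSUMED desk-scale
#'   default 1920 um stands in for the centimeter-scale experimental column
#'   (deep enough that supplements are not exhausted within 7 generations).
#' @return a `medium_spec` object.
#' @export
medium_spec <- function(supplemented_lysine = 0,
                        supplemented_adenine = 0,
                        initial_glucose = 110000,
                        agarose_height = 1920) {
  if (supplemented_lysine < 0 || supplemented_adenine < 0 ||
      initial_glucose < 0)
    abort("invalid-spec: concentrations must be >= 0")
  if (agarose_height <= 0) abort("invalid-spec: agarose height must be > 0")
  structure(
    list(supplemented_lysine = supplemented_lysine,
         supplemented_adenine = supplemented_adenine,
         initial_glucose = initial_glucose,
         agarose_height = agarose_height),
    class = "medium_spec")
}

#' Supplemented (competition) medium
#'
#' Convenience wrapper for the standard supplemented medium: 650 uM lysine
#' and 430 uM adenine, under which all three strains grow independently and
#' purely compete for the shared resource.
#'
#' @inheritParams medium_spec
#' @return a `medium_spec`.
#' @export
medium_supplemented <- function(agarose_height = 1920)
  medium_spec(650, 430, agarose_height = agarose_height)

#' Simulation configuration
#'
#' Geometry, numerical cadence, and variant flags for the spatial engine.
#' The printed physical constants are defaults: cells sit on a 5 um lattice,
#' concentration fields live on a 15 um community/air grid and a 60 um
#' agarose grid, the diffusion step is t_u = 3.5 s, cell states are examined
#' every tau = 6 min, and D is 360 um^2/s in agarose, up to 20 um^2/s inside
#' the community (proportional to voxel occupancy), and 0 in air. The
#' explicit solver sub-steps each t_u internally to satisfy the 3-D
#' stability bound `D dt / h^2 <= 1/6`, which the printed t_u alone would
#' violate on the agarose grid.
#'
#' @param domain_width lateral domain size (um); the domain is a periodic
#'   square and must be a multiple of 60 um. Desk-scale default 600 um.
#' @param domain_height height of the cell/community domain above the
#'   agarose (um); must be a multiple of 15 um.
#' @param cell_pitch cell site size (um).
#' @param community_grid community/air field grid (um); integer multiple of
#'   `cell_pitch`.
#' @param agarose_grid agarose field grid (um); integer multiple of
#'   `community_grid`.
#' @param diffusion_timestep_tu physical diffusion time step t_u (seconds).
#' @param cell_update_interval_tau cell update interval tau (minutes).
#' @param D_agarose,D_community_max,D_air diffusion coefficients (um^2/s).
#' @param vertical_bud_probability probability that a fully enclosed mother
#'   buds directly upward instead of displacing a lateral neighbor upward.
#' @param enclosure_radius_cells lateral search radius (in cells) for empty
#'   space before a mother counts as enclosed ("roughly five cells").
#' @param glucose_monod_K Monod constant of the shared resource (uM);
#'   ASSUMED.
#' @param mixing_interval_hr interval between complete randomizations of the
#'   cell arrangement (hr), or `NA` for unperturbed growth; 12 hr for the
#'   periodically mixed protocol.
#' @param target_generations stop once the community has grown this many
#'   doublings (log2 of live-cell fold change).
#' @param max_hours hard stop (hr).
#' @param excess_release_factor scales all release rates; 200 reproduces the
#'   excess-release delocalization variant.
#' @param instant_distribution if `TRUE`, released metabolites are instantly
#'   distributed: after every t_u each field is replaced by its
#'   volume-weighted spatial mean over community + agarose.
#' @param uniform_D if `TRUE`, use the agarose diffusion coefficient
#'   everywhere in the community domain as well (the single-coefficient
#'   variant; substantially slower because of the stability sub-stepping).
#' @param record_every_tau record a time-series row every this many tau
#'   windows.
#' @param snapshot_every_gen record a lattice snapshot (and association
#'   index) every this many generations.
#' @param rng_seed optional integer; if supplied, [run_spatial()] seeds the
#'   session RNG with it, making trajectories bit-reproducible.
#' @return a `sim_config` object.
#' @export
sim_config <- function(domain_width = 600,
                       domain_height = 240,
                       cell_pitch = 5,
                       community_grid = 15,
                       agarose_grid = 60,
                       diffusion_timestep_tu = 3.5,
                       cell_update_interval_tau = 6,
                       D_agarose = 360,
                       D_community_max = 20,
                       D_air = 0,
                       vertical_bud_probability = 0.7,
                       enclosure_radius_cells = 5,
                       glucose_monod_K = 50,
                       mixing_interval_hr = NA_real_,
                       target_generations = 6,
                       max_hours = 96,
                       excess_release_factor = 1,
                       instant_distribution = FALSE,
                       uniform_D = FALSE,
                       record_every_tau = 1,
                       snapshot_every_gen = 0.5,
                       rng_seed = NULL) {
  if (community_grid %% cell_pitch != 0)
    abort("invalid-config: community_grid must be a multiple of cell_pitch")
  if (agarose_grid %% community_grid != 0)
    abort("invalid-config: agarose_grid must be a multiple of community_grid")
  if (domain_width %% agarose_grid != 0)
    abort("invalid-config: domain_width must be a multiple of agarose_grid")
  if (domain_height %% community_grid != 0)
    abort("invalid-config: domain_height must be a multiple of community_grid")
  if (vertical_bud_probability < 0 || vertical_bud_probability > 1)
    abort("invalid-config: vertical_bud_probability must lie in [0, 1]")
  tau_s <- cell_update_interval_tau * 60
  if (tau_s < 2 * diffusion_timestep_tu)
    abort("invalid-config: tau must be much larger than t_u")
  structure(
    list(domain_width = domain_width, domain_height = domain_height,
         cell_pitch = cell_pitch, community_grid = community_grid,
         agarose_grid = agarose_grid,
         diffusion_timestep_tu = diffusion_timestep_tu,
         cell_update_interval_tau = cell_update_interval_tau,
         D_agarose = D_agarose, D_community_max = D_community_max,
         D_air = D_air,
         vertical_bud_probability = vertical_bud_probability,
         enclosure_radius_cells = enclosure_radius_cells,
         glucose_monod_K = glucose_monod_K,
         mixing_interval_hr = mixing_interval_hr,
         target_generations = target_generations,
         max_hours = max_hours,
         excess_release_factor = excess_release_factor,
         instant_distribution = instant_distribution,
         uniform_D = uniform_D,
         record_every_tau = record_every_tau,
         snapshot_every_gen = snapshot_every_gen,
         rng_seed = rng_seed),
    class = "sim_config")
}

# ---- config files ---------------------------------------------------------

#' Read or write a configuration document
#'
#' Configurations (strains, medium, simulation settings, protocol) are
#' persisted as a flat, versioned YAML document. The writer prepends a
#' comment block mapping entries to their conventional symbols (alpha, K,
#' gamma_A, beta_L, d, t_u, tau, D) and flags ASSUMED defaults.
#'
#' @param x a named list with any of `strains` (list of [strain_spec()]),
#'   `medium` ([medium_spec()]), `config` ([sim_config()]), `protocol`
#'   (a [protocol()]).
#' @param path file path.
#' @return `read_config_file()` returns the reconstructed list;
#'   `write_config_file()` returns `path` invisibly.
#' @export
write_config_file <- function(x, path) {
  doc <- list(format = "crossfeedr-config", version = 1L)
  if (!is.null(x$strains))
    doc$strains <- lapply(x$strains, function(s) unclass(s))
  if (!is.null(x$medium)) doc$medium <- unclass(x$medium)
  if (!is.null(x$config)) doc$config <- unclass(x$config)
  if (!is.null(x$protocol)) doc$protocol <- unclass(x$protocol)
  header <- c(
    "# crossfeedr configuration (units: um, hr, fmole, uM where stated)",
    "#   quota_alpha       -> alpha_L / alpha_A (fmole per division)",
    "#   glucose_quota     -> alpha_G (fmole per division)      [ASSUMED]",
    "#   r_max             -> r_m,i (per hr)                    [ASSUMED]",
    "#   monod_K           -> K_i = Monod constant (uM)         [ASSUMED]",
    "#   release_rate_gamma   -> gamma_A (fmole/cell/hr)        [ASSUMED]",
    "#   release_on_death_beta-> beta_L (fmole per death)       [ASSUMED]",
    "#   release_fraction_d   -> d (dimensionless)",
    "#   death_rate        -> d_R, d_G, d_C (per hr)            [ASSUMED]",
    "#   diffusion_timestep_tu -> t_u (s); cell_update_interval_tau -> tau (min)",
    "#   D_agarose/D_community_max/D_air -> D (um^2/s)")
  writeLines(c(header, yaml::as.yaml(doc)), path)
  invisible(path)
}

#' @rdname write_config_file
#' @export
read_config_file <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "crossfeedr-config"))
    abort("not a crossfeedr configuration document")
  out <- list()
  if (!is.null(doc$strains))
    out$strains <- lapply(doc$strains, function(s) do.call(strain_spec, s))
  if (!is.null(doc$medium)) out$medium <- do.call(medium_spec, doc$medium)
  if (!is.null(doc$config)) {
    cfg <- doc$config
    cfg$mixing_interval_hr <- cfg$mixing_interval_hr %||% NA_real_
    out$config <- do.call(sim_config, cfg)
  }
  if (!is.null(doc$protocol)) out$protocol <- do.call(protocol, doc$protocol)
  out
}
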