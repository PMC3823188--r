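test_that("uptake_window implements clamped Michaelis-Menten uptake", {
  # half-saturation: S = K -> rate vm/2
  expect_equal(uptake_window(vm = 2, K = 1e-6, S = 1e-6, store = 0,
                             quota = 2, t_u = 1), 1)
  # zero concentration -> zero uptake
  expect_equal(uptake_window(2, 1e-6, 0, 0, 2, 1), 0)
  # quota met -> stops consuming regardless of concentration
  expect_equal(uptake_window(2, 1e-6, 1, 2, 2, 1), 0)
  # share of available voxel mass caps the draw
  expect_equal(uptake_window(2, 1e-6, 1, 0, 2, 1, available = 0.3), 0.3)
})

test_that("the engine's uptake matches the single-cell rule", {
  # one live cell, one t_u, no diffusion possible out of its voxel (all
  # neighbors are air, D = 0)
  st <- mini_state(strains = list(simple_strain()),
                   medium = medium_spec(agarose_height = 240))
  seed_cells(st, cbind(5L, 5L, 1L), 1L)
  st$store_req[5, 5, 1] <- 0; st$store_glc[5, 5, 1] <- 2  # glucose quota met
  S0 <- uM_to_conc(10)
  st$SL_c[2, 2, 1] <- S0
  step_fields(st, 1)
  vm <- derive_vm(simple_strain())
  expected <- uptake_window(vm, uM_to_conc(1), S0, 0, 2, 3.5 / 3600,
                            available = S0 * 15^3)
  expect_equal(st$store_req[5, 5, 1], expected, tolerance = 1e-12)
  # interface exchange with the agarose also moved some mass; ledger agrees
  expect_equal(st$led_con[["L"]], expected, tolerance = 1e-12)
})

test_that("cells divide exactly when both quotas are met", {
  st <- mini_state(strains = list(simple_strain()))
  seed_cells(st, cbind(c(5L, 12L, 20L), c(5L, 12L, 20L), c(1L, 1L, 1L)),
             rep(1L, 3))
  # cell 1: both quotas met; cell 2: only required; cell 3: neither
  st$store_req[5, 5, 1] <- 2;  st$store_glc[5, 5, 1] <- 2
  st$store_req[12, 12, 1] <- 2; st$store_glc[12, 12, 1] <- 0.5
  st$store_req[20, 20, 1] <- 0.1; st$store_glc[20, 20, 1] <- 0.1
  ev <- attempt_divisions(st)
  expect_equal(nrow(ev), 1)
  expect_equal(sum(st$strain != 0L), 4)
  # mother's stores dropped by one quota; daughter starts empty
  expect_equal(st$store_req[5, 5, 1], 0)
  d <- arrayInd(ev$daughter, dim(st$strain))
  expect_equal(d[3], 1L)  # lateral placement on the surface
  expect_equal(st$store_req[d], 0)
  # no cell at quota -> no events
  expect_equal(nrow(attempt_divisions(st)), 0)
})

test_that("two ready cells both divide within one window", {
  st <- mini_state(strains = list(simple_strain()))
  seed_cells(st, cbind(c(6L, 30L), c(6L, 30L), c(1L, 1L)), c(1L, 1L))
  st$store_req[cbind(c(6, 30), c(6, 30), c(1, 1))] <- 2
  st$store_glc[cbind(c(6, 30), c(6, 30), c(1, 1))] <- 2
  ev <- attempt_divisions(st)
  expect_equal(nrow(ev), 2)
  expect_equal(sum(st$strain != 0L), 4)
})

test_that("an adjacent empty site takes the daughter with no pushing", {
  st <- mini_state(strains = list(simple_strain()))
  seed_cells(st, cbind(9L, 9L, 1L), 1L)
  res <- place_daughter(st, c(9, 9, 1))
  expect_equal(nrow(res$chain), 0)
  expect_equal(res$mode, "lateral")
  expect_equal(max(abs(res$daughter[1:2] - c(9, 9))), 1)  # adjacent
  expect_equal(res$daughter[3], 1)
})

test_that("an enclosed mother buds upward with probability 0.7", {
  build <- function() {
    st <- mini_state(strains = list(simple_strain()))
    pos <- as.matrix(expand.grid(i = 9:19, j = 9:19, k = 1L))
    seed_cells(st, pos, rep(1L, nrow(pos)))  # 11x11 slab: radius-5 enclosure
    st
  }
  set.seed(77)
  n_up <- 0; n_trials <- 400
  for (t in seq_len(n_trials)) {
    st <- build()
    res <- place_daughter(st, c(14, 14, 1))
    expect_true(res$mode %in% c("up", "side_up"))
    if (res$mode == "up") {
      n_up <- n_up + 1
      expect_equal(res$daughter, c(14, 14, 2))
    } else {
      # a lateral neighbor was displaced upward and its site taken
      expect_equal(res$daughter[3], 1)
      expect_equal(max(abs(res$daughter[1:2] - c(14, 14))), 1)
      expect_equal(st$strain[res$daughter[1], res$daughter[2], 2], 1L)
    }
  }
  # binomial(400, 0.7): 3 sigma ~ 0.069
  expect_gt(n_up / n_trials, 0.7 - 0.07)
  expect_lt(n_up / n_trials, 0.7 + 0.07)
})

test_that("equidistant empty rays are chosen uniformly", {
  # mother at the center of a filled 11x11 slab with two holes at distance 3
  # along +x and -x; every other ray is blocked to beyond the radius
  build <- function() {
    st <- mini_state(strains = list(simple_strain()), width = 240, height = 15)
    pos <- as.matrix(expand.grid(i = 14:34, j = 14:34, k = 1L))
    seed_cells(st, pos, rep(1L, nrow(pos)))
    st$strain[24 + 3, 24, 1] <- 0L  # +x hole at r = 3
    st$strain[24 - 3, 24, 1] <- 0L  # -x hole at r = 3
    st
  }
  set.seed(101)
  st0 <- build()
  n_plus <- 0; n <- 1e4
  for (t in seq_len(n)) {
    st <- copy_state(st0)
    res <- place_daughter(st, c(24, 24, 1))
    expect_equal(res$mode, "lateral")
    expect_equal(res$daughter[2], 24)
    if (res$daughter[1] == 25) n_plus <- n_plus + 1
    else expect_equal(res$daughter[1], 23)
  }
  expect_equal(n_plus / n, 0.5, tolerance = 0.04)  # 50% +/- 2 points
})

test_that("death_step is binomial and only partner-type cells release", {
  st <- mini_state(strains = list(
    strain_spec("R", "lysine", death_rate = 0),
    strain_spec("G", "adenine", death_rate = 0.1,
                release_mode = "on_death", release_on_death_beta = 24),
    strain_spec("C", "lysine", death_rate = 0)),
    width = 600, height = 15)
  # death rate 0 -> no deaths
  set.seed(13)
  pos <- as.matrix(expand.grid(i = seq(1, 120, 2), j = seq(1, 120, 2), k = 1L))
  seed_cells(st, pos[1:3000, ], rep(1L, 3000))
  expect_equal(sum(death_step(st)$deaths), 0)
  # 1e4 G cells at p = 0.1 * tau = 0.01 -> about 100 deaths, sd 10
  st2 <- mini_state(strains = st$strains, width = 600, height = 15)
  pos2 <- as.matrix(expand.grid(i = 1:100, j = 1:100, k = 1L))
  seed_cells(st2, pos2, rep(2L, 1e4))
  d <- death_step(st2)
  expect_equal(d$deaths[2], 100, tolerance = 0.3)
  # dying G released beta_L each; R and C release nothing on death
  expect_equal(sum(st2$death_src_L), 24 * d$deaths[2])
  expect_equal(sum(st2$death_src_A), 0)
  # dead cells are retained in place
  expect_equal(sum(st2$strain < 0L), d$deaths[2])
})

test_that("the cell-count ledger balances exactly", {
  set.seed(19)
  st <- mini_state(medium = medium_supplemented(agarose_height = 240))
  init_random_lawn(st, 6000)
  n0 <- sum(st$strain > 0L)
  for (i in 1:40) tau_step(st)
  cc <- strain_counts(st)
  expect_equal(sum(cc$live) + sum(cc$dead),
               n0 + sum(st$births))
  expect_equal(sum(cc$dead), sum(st$deaths))
  # no two cells ever share a site (by construction of the label array) and
  # every cell is supported
  assert_supported(st)
  succeed()
})

test_that("abundant nutrients give log2 growth at r_max within 5%", {
  # single strain, saturating lysine (K = 1 uM against 650 uM), no death
  s <- strain_spec("R", "lysine", quota_alpha = 2, glucose_quota = 2,
                   r_max = 0.35, monod_K = 1, death_rate = 0)
  set.seed(23)
  st <- mini_state(strains = list(s),
                   medium = medium_supplemented(agarose_height = 960))
  init_random_lawn(st, 2000, ratios = 1)
  rows <- list()
  for (i in 1:240) {
    tau_step(st)
    rows[[i]] <- c(t = st$time_hr, gen = generations(st))
    if (generations(st) >= 2.7) break
  }
  tr <- do.call(rbind, rows)
  # fit between generations 1 and 2.5 (past the initial-store transient,
  # before any supplement depletion)
  sel <- tr[, "gen"] >= 1 & tr[, "gen"] <= 2.5
  fit <- lm(tr[sel, "gen"] ~ tr[sel, "t"])
  r_obs <- log(2) * coef(fit)[2]
  expect_equal(unname(r_obs), 0.35, tolerance = 0.05)
})

test_that("identical seeds give bitwise-identical trajectories", {
  run <- function() {
    cfg <- sim_config(domain_width = 180, domain_height = 120,
                      rng_seed = 99, target_generations = 2, max_hours = 12)
    run_spatial(cfg, protocol(density = 6000), medium_spec(agarose_height = 240),
                default_panel(0.02))
  }
  a <- run(); b <- run()
  expect_identical(a$series, b$series)
  expect_identical(a$state$strain, b$state$strain)
  expect_identical(a$state$store_req, b$state$store_req)
  expect_identical(a$state$SL_c, b$state$SL_c)
})
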