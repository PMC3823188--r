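test_that("hand-built fixtures give exact association indexes", {
  # every qualifying R has two partner neighbors, every qualifying C one
  m <- fixture_lattice("two_to_one")
  ai <- association_index(m, 1L, 3L, 2L, wrap = FALSE)
  expect_equal(ai$index, 2)
  expect_equal(ai$n_focal_a, 1L)
  expect_equal(ai$n_focal_b, 1L)
  # mirror symmetry under swapping R and C: exactly 1
  ai2 <- association_index(fixture_lattice("mirror"), 1L, 3L, 2L,
                           wrap = FALSE)
  expect_equal(ai2$index, 1)
  # 3-D fixture: R column touches G column diagonally, C column isolated;
  # C has no different-population neighbor -> undefined
  ai3 <- association_index(fixture_lattice("column_pair"), 1L, 3L, 2L)
  expect_equal(ai3$status, "undefined")
})

test_that("association_index equals the brute-force oracle exactly", {
  set.seed(55)
  for (rep in 1:12) {
    d <- c(sample(5:12, 1), sample(5:12, 1), sample(3:6, 1))
    labels <- array(sample(c(0L, 0L, 1L, 2L, 3L, -1L, -2L), prod(d), TRUE), d)
    got <- association_index(labels, 1L, 3L, 2L, mode = "full26")
    want <- brute_assoc(labels, 1L, 3L, 2L)
    if (is.na(want)) {
      expect_equal(got$status, "undefined")
    } else {
      expect_equal(got$index, unname(want), tolerance = 1e-12)
    }
  }
  # 2-D planar mode against the same oracle
  for (rep in 1:6) {
    m <- matrix(sample(c(0L, 1L, 2L, 3L), 100, TRUE), 10, 10)
    got <- association_index(m, 1L, 3L, 2L, mode = "planar8")
    want <- brute_assoc(m, 1L, 3L, 2L, mode = "planar8")
    if (is.na(want)) expect_equal(got$status, "undefined")
    else expect_equal(got$index, unname(want), tolerance = 1e-12)
  }
})

test_that("swapping the focal classes inverts the index", {
  set.seed(66)
  for (rep in 1:8) {
    labels <- array(sample(c(0L, 1L, 2L, 3L), 8 * 8 * 4, TRUE), c(8, 8, 4))
    a <- association_index(labels, 1L, 3L, 2L)
    b <- association_index(labels, 3L, 1L, 2L)
    if (a$status == "ok" && b$status == "ok" && is.finite(a$index) &&
        a$index > 0)
      expect_equal(a$index, 1 / b$index, tolerance = 1e-12)
  }
})

test_that("label permutation centers the index on 1", {
  set.seed(77)
  # a reasonably dense lawn: the ratio-of-means estimator is biased ~1/n
  # for small focal counts, so use enough cells for the null to center
  st <- mini_state(width = 480, height = 15)
  init_random_lawn(st, 10000)
  lab0 <- st$strain
  occ <- which(lab0 != 0L)
  idx <- replicate(200, {
    lab <- lab0
    lab[occ] <- lab0[occ][sample.int(length(occ))]
    association_index(lab, 1L, 3L, 2L)$index
  })
  expect_equal(mean(idx), 1, tolerance = 0.05)
})

test_that("dead cells are excluded by default but can be included", {
  m <- fixture_lattice("two_to_one")
  m[3, 3] <- -2L  # kill one partner next to R
  ai <- association_index(m, 1L, 3L, 2L, wrap = FALSE)
  # R keeps G(1,1); C's only partner neighbor is now dead -> C unqualified
  # (its sole different-population neighbor was that partner)
  expect_equal(ai$status, "undefined")
  ai2 <- association_index(m, 1L, 3L, 2L, wrap = FALSE, include_dead = TRUE)
  expect_equal(ai2$index, 2)
})

test_that("population_ratio counts live cells and flags extinction", {
  st <- mini_state()
  seed_cells(st, cbind(c(1L, 2L, 3L, 4L), c(1L, 1L, 1L, 1L),
                       rep(1L, 4)), c(1L, 1L, 1L, 3L))
  expect_equal(population_ratio(st, "R", "C"), 3)
  st$strain[4, 1, 1] <- -3L  # the only cheater dies
  expect_warning(r <- population_ratio(st, "R", "C"), "extinct")
  expect_equal(r, Inf)
})

test_that("fitness_advantage recovers exact and noisy log-linear slopes", {
  g <- seq(0, 8, by = 0.25)
  # exact: ratio (1.05)^g -> 5% per generation
  s <- tibble::tibble(generation = g, ratio = 1.05^g)
  expect_equal(fitness_advantage(s), 5, tolerance = 1e-9)
  # constant ratio -> 0%
  expect_equal(fitness_advantage(tibble::tibble(generation = g, ratio = 2)),
               0, tolerance = 1e-12)
  # window not covered -> error
  expect_error(fitness_advantage(s[s$generation < 4, ]), "cover")
  # noisy series: mean estimate over 100 seeds within 3 sd of the truth
  set.seed(88)
  est <- replicate(100, {
    noisy <- tibble::tibble(generation = g,
                            ratio = exp(log(1.03) * g + rnorm(length(g), 0, 0.01)))
    fitness_advantage(noisy)
  })
  expect_lt(abs(mean(est) - 3), 3 * sd(est))
})

test_that("region_split_metrics partitions the spot community", {
  st <- mini_state(width = 600, height = 60)
  set.seed(12)
  init_spot(st, density = 8e4, diameter = 200)
  m <- region_split_metrics(st)
  expect_equal(m$region, c("center", "front"))
  # before growth: everything is center, the front is empty
  expect_equal(m$n_live[m$region == "front"], 0)
  expect_equal(m$assoc_status[m$region == "front"], "undefined")
  expect_equal(sum(m$n_live), sum(st$strain > 0L))
  # after growth the two regions partition the population
  cfg <- sim_config(domain_width = 600, domain_height = 240, rng_seed = 2,
                    target_generations = 1.5, max_hours = 20,
                    record_every_tau = 10)
  traj <- run_spatial(cfg, protocol("spot", density = 8e4,
                                    spot_diameter = 200),
                      medium_spec(agarose_height = 240), default_panel())
  m2 <- region_split_metrics(traj)
  expect_equal(sum(m2$n_live), sum(traj$state$strain > 0L))
  expect_gt(m2$n_live[2], 0)
})

test_that("the 3-D association series starts near 1 on random lawns", {
  idx0 <- vapply(1:6, function(s) {
    cfg <- sim_config(domain_width = 600, domain_height = 60, rng_seed = s,
                      target_generations = 0.1, max_hours = 0.2)
    traj <- run_spatial(cfg, protocol(density = 3000),
                        medium_spec(agarose_height = 240), default_panel())
    association_index_3d_timeseries(traj)$index[1]
  }, numeric(1))
  expect_equal(mean(idx0), 1, tolerance = 0.05)
})
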