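cfg8 <- chemostat_config(supply_conc = 20, doubling = 8)

test_that("generators are deterministic under a fixed seed", {
  a <- generate_chemostat_series(phen$LA, cfg8, times = seq(0, 48, 3),
                                 seed = 42)
  b <- generate_chemostat_series(phen$LA, cfg8, times = seq(0, 48, 3),
                                 seed = 42)
  expect_identical(a$live_per_ml, b$live_per_ml)
  expect_identical(a$released_uM, b$released_uM)
  c <- generate_chemostat_series(phen$LA, cfg8, times = seq(0, 48, 3),
                                 seed = 43)
  expect_false(identical(a$live_per_ml, c$live_per_ml))
  expect_equal(attr(a, "seed"), 42)
})

test_that("zero noise reproduces the latent forward model exactly", {
  obs <- generate_chemostat_series(phen$LA, cfg8, times = seq(0, 48, 3),
                                   noise = noise_model(0, 0), seed = 1)
  latent <- simulate_chemostat(phen$LA, cfg8, t_end = 48,
                               times = seq(0, 48, 3))
  expect_equal(obs$live_per_ml, latent$live_per_ml)
  expect_equal(obs$released_uM, latent$released_uM)
})

test_that("noise is multiplicative, mean-preserving and channel-specific", {
  nm <- noise_model(cv_density = 0.075, cv_metabolite = 0.10)
  set.seed(99)
  x <- cosmor:::apply_noise(rep(100, 2e5), nm$cv_density)
  expect_equal(mean(x), 100, tolerance = 0.002)
  expect_equal(sd(x) / mean(x), 0.075, tolerance = 0.02)
  expect_true(all(x > 0))
  expect_error(noise_model(-0.1), ">= 0")
})

test_that("starvation generator obeys its closed forms", {
  # live mode without death: metabolite exactly linear in N0 * t
  s <- generate_starvation_series(N0 = 1e6, release_mode = "live", r = 0.4,
                                  death = 0, dead0_frac = 0,
                                  noise = noise_model(0, 0))
  expect_equal(s$metabolite_uM, 0.4 * 1e6 * s$time_h * 1e-6)
  expect_equal(s$live_per_ml, rep(1e6, nrow(s)))
  # dead mode: metabolite tracks deaths, not the initial dead pool
  s2 <- generate_starvation_series(N0 = 1e6, release_mode = "dead",
                                   r_dead = 30, death = 0.01,
                                   dead0_frac = 0.1, noise = noise_model(0, 0))
  deaths <- 1e6 * (1 - exp(-0.01 * s2$time_h))
  expect_equal(s2$metabolite_uM, 30 * deaths * 1e-6)
  expect_equal(s2$dead_per_ml, 1e5 + deaths)
})

test_that("the mode comparison recovers the generating release mode under noise", {
  hits <- c(live = 0, dead = 0)
  for (mode in c("live", "dead")) {
    for (seed in 1:100) {
      s <- generate_starvation_series(release_mode = mode, seed = seed)
      cmp <- compare_release_models(s$time_h, s$live_per_ml, s$dead_per_ml,
                                    s$metabolite_uM)
      hits[mode] <- hits[mode] + (cmp$preferred == mode)
    }
  }
  expect_gte(hits[["live"]], 95)
  expect_gte(hits[["dead"]], 95)
})

test_that("estimators are unbiased on noisy synthetic chemostat series", {
  latent <- simulate_chemostat(phen$LA, cfg8, t_end = 96,
                               times = seq(0, 96, 3))
  vals <- numeric(200)
  set.seed(4)
  s <- sqrt(log(1 + 0.075^2))
  for (i in seq_along(vals)) {
    noisy <- latent
    noisy$live_per_ml <- cosmor:::apply_noise(latent$live_per_ml, 0.075)
    noisy$released_uM <- cosmor:::apply_noise(latent$released_uM, 0.10)
    vals[i] <- estimate_release_regression(noisy, cfg8$dil)$value
  }
  expect_equal(mean(vals), 0.27, tolerance = 0.02)
})

test_that("the community-trajectory generator books dilutions invertibly", {
  g <- generate_cosmo_trajectory(phen, t_end = 120,
                                 dilution_threshold = 1e7,
                                 dilution_factor = 10,
                                 noise = noise_model(0, 0), seed = 5)
  ev <- attr(g, "events")
  expect_gt(nrow(ev), 0)
  expect_true(all(g$NL_per_ml + g$NA_per_ml <= 1e7 * 10))
  acc <- accumulate_densities(g$time_h, g$NL_per_ml + g$NA_per_ml, ev)
  ref <- simulate_wellmixed(phen, t_end = 120, times = g$time_h)
  expect_equal(acc, ref$NL_per_ml + ref$NA_per_ml, tolerance = 1e-10)
  # no threshold crossing -> no events
  g0 <- generate_cosmo_trajectory(phen, t_end = 24,
                                  dilution_threshold = 1e12,
                                  noise = noise_model(0, 0), seed = 5)
  expect_equal(nrow(attr(g0, "events")), 0)
  expect_equal(g0$dilution_factor, rep(1, nrow(g0)))
})

test_that("the fitted rate covers the latent rate on noisy dilution series", {
  covered <- 0
  reps <- 60
  base <- generate_cosmo_trajectory(phen, t_end = 120,
                                    dilution_threshold = 1e7,
                                    noise = noise_model(0, 0), seed = 1)
  ev <- attr(base, "events")
  latent_acc <- accumulate_densities(base$time_h,
                                     base$NL_per_ml + base$NA_per_ml, ev)
  truth <- fit_growth_rate(base$time_h, latent_acc, t_min = 70)$value
  set.seed(17)
  for (i in 1:reps) {
    tot <- cosmor:::apply_noise(latent_acc, 0.075)
    est <- fit_growth_rate(base$time_h, tot, t_min = 70)
    covered <- covered + (abs(est$value - truth) <= 2 * est$sem)
  }
  expect_gte(covered, 0.9 * reps)
})
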