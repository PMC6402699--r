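la <- phen$LA
cfg8 <- chemostat_config(supply_conc = 20, doubling = 8)

test_that("flow and dilution rates derive from the doubling time", {
  res <- dilution_rate_from_doubling(19, 8)
  expect_equal(res$flow_ml_h, 1.646, tolerance = 3e-4)
  expect_equal(res$dil_per_h, log(2) / 8)
  expect_equal(dilution_rate_from_doubling(19, Inf)$flow_ml_h, 0)
  expect_equal(dilution_rate_from_doubling(19, 5.5)$flow_ml_h, 19 * log(2) / 5.5)
  expect_error(dilution_rate_from_doubling(-1, 8), "> 0")
})

test_that("the chemostat settles where net growth equals the dilution rate", {
  ser <- simulate_chemostat(la, cfg8, t_end = 96, times = seq(0, 96, 1))
  ss <- chemostat_steady_state(ser)
  b <- moser_birth_rate(ss$limiting, la$birth)
  expect_lt(abs(b - la$death - cfg8$dil), 1e-5)
  # steady live density ~ reservoir concentration / consumption per birth
  expect_equal(ss$live, 20e6 / 5.4, tolerance = 0.1)
  # zero release gives identically zero released metabolite
  la0 <- strain_phenotype(la$birth, la$death, la$consumption, release = 0)
  ser0 <- simulate_chemostat(la0, cfg8, t_end = 48)
  expect_equal(ser0$released_uM, rep(0, nrow(ser0)), tolerance = 1e-12)
})

test_that("steady-state estimators recover the generating phenotypes", {
  ser <- simulate_chemostat(la, cfg8, t_end = 96, times = seq(0, 96, 1))
  ss <- chemostat_steady_state(ser)
  cons <- estimate_consumption_ss(20, cfg8$dil, ss$limiting,
                                  cfg8$dil + la$death, ss$live)
  expect_equal(cons$exact, 5.4, tolerance = 0.01)
  expect_equal(cons$approx, 20 / ss$live / 1e-6)  # the stated approximation
  expect_equal(estimate_death_ss(cfg8$dil, ss$dead, ss$live), 0.0024,
               tolerance = 0.02)
  expect_equal(estimate_release_ss(cfg8$dil, ss$released, ss$live), 0.27,
               tolerance = 0.02)
  # hand-checked arithmetic
  expect_equal(estimate_death_ss(0.0866, 0.0277 * 3.2e6, 3.2e6), 0.0024,
               tolerance = 0.001)
  expect_equal(estimate_release_ss(0.0866, 10, 3.2e6), 0.27, tolerance = 0.01)
  expect_equal(estimate_release_ss(0.1, 0, 1e6), 0)
  expect_equal(estimate_consumption_ss(20, 0.1, 20, 0.1, 1e6)$exact, 0)
  expect_error(estimate_death_ss(0.1, 1, 0), "> 0")
})

test_that("the exponentially weighted trapezoid integral matches hand values", {
  expect_equal(exp_weighted_integral(c(0, 1, 2), c(0, 1, 2), 0), c(0, 0.5, 2))
  t <- seq(0, 10, 0.5)
  expect_equal(exp_weighted_integral(t, rep(3, length(t)), 0), 3 * t)
  # f = exp(-dil t) makes the weighted integrand constant: grid-exact
  expect_equal(exp_weighted_integral(t, exp(-0.2 * t), 0.2), t)
  expect_error(exp_weighted_integral(c(0, 0, 1), c(1, 1, 1), 0),
               "increasing")
  expect_error(exp_weighted_integral(0, 1, 0), "2 points")
})

test_that("regression estimators recover release and death from full time courses", {
  ser <- simulate_chemostat(la, cfg8, t_end = 96, times = seq(0, 96, 1))
  rel <- estimate_release_regression(ser, cfg8$dil)
  expect_equal(rel$value, 0.27, tolerance = 0.005)
  dth <- estimate_death_regression(ser, cfg8$dil)
  expect_equal(dth$value, 0.0024, tolerance = 0.01)
  # steady-state and regression estimators agree on converged series
  ss <- chemostat_steady_state(ser)
  expect_equal(rel$value, estimate_release_ss(cfg8$dil, ss$released, ss$live),
               tolerance = 0.03)
  expect_equal(dth$value, estimate_death_ss(cfg8$dil, ss$dead, ss$live),
               tolerance = 0.03)
  # no deaths: dead pool only washes out, slope 0
  t <- seq(0, 48, 2)
  fake <- data.frame(time_h = t, live_per_ml = rep(1e6, length(t)),
                     dead_per_ml = 1e4 * exp(-0.1 * t),
                     released_uM = rep(0, length(t)))
  expect_equal(estimate_death_regression(fake, 0.1)$value, 0,
               tolerance = 1e-10)
  expect_error(estimate_release_regression(fake[1:2, ], 0.1), "3 points")
})

test_that("live release and rate-matched dead release are mathematically equivalent", {
  rd <- la$release / la$death
  cfg_dead <- chemostat_config(supply_conc = 20, doubling = 8,
                               release_mode = "dead",
                               dead_release_amount = rd)
  ser_live <- simulate_chemostat(la, cfg8, 96, times = seq(0, 96, 1))
  ser_dead <- simulate_chemostat(la, cfg_dead, 96, times = seq(0, 96, 1))
  expect_equal(ser_live$released_uM, ser_dead$released_uM, tolerance = 1e-10)
  # and the mode comparison on such data is indeterminate
  cmp <- compare_release_models(ser_live$time_h, ser_live$live_per_ml,
                                ser_live$dead_per_ml, ser_live$released_uM,
                                dil = cfg8$dil)
  expect_equal(cmp$preferred, "indeterminate")
})

test_that("release-mode comparison identifies the generating mode structurally", {
  quiet <- function(x) suppressWarnings(x)
  s_live <- generate_starvation_series(release_mode = "live",
                                       noise = noise_model(0, 0))
  cmp <- quiet(compare_release_models(s_live$time_h, s_live$live_per_ml,
                                      s_live$dead_per_ml,
                                      s_live$metabolite_uM))
  expect_equal(cmp$preferred, "live")
  expect_gt(cmp$live$r_squared, cmp$dead$r_squared)
  s_dead <- generate_starvation_series(release_mode = "dead",
                                       noise = noise_model(0, 0))
  cmp <- quiet(compare_release_models(s_dead$time_h, s_dead$live_per_ml,
                                      s_dead$dead_per_ml,
                                      s_dead$metabolite_uM))
  expect_equal(cmp$preferred, "dead")
  # constant death, no initial dead pool: dead exactly proportional to the
  # integrated live density -> indeterminate
  s_col <- generate_starvation_series(release_mode = "live", death = 0.01,
                                      dead0_frac = 0, noise = noise_model(0, 0))
  cmp <- quiet(compare_release_models(s_col$time_h, s_col$live_per_ml,
                                      s_col$dead_per_ml, s_col$metabolite_uM))
  expect_equal(cmp$preferred, "indeterminate")
  # constant regressor: that model is inapplicable
  t <- 0:5
  cmp <- quiet(compare_release_models(t, rep(1e6, 6), rep(1e4, 6),
                                      0.1 * t))
  expect_false(cmp$dead$applicable)
  expect_equal(cmp$preferred, "live")
  expect_error(compare_release_models(0:2, 1:3, 1:3, 1:3), "4 points")
})

test_that("dead-release plausibility arithmetic is a pure unit conversion", {
  expect_equal(dead_release_conc(0.12, 1e5), 0.012)
  expect_equal(dead_release_conc(0.12, 0), 0)
  expect_equal(dead_release_required(10, 1e5), 100)
  expect_equal(dead_release_required(dead_release_conc(7, 2e5), 2e5), 7)
  expect_error(dead_release_required(1, 0), "> 0")
})

test_that("batch consumption estimators recover constructed and simulated truths", {
  # constructed slope
  N <- seq(1e6, 2e7, length.out = 8)
  M <- 100 - 3 * (N - 1e6) * 1e-6
  expect_equal(estimate_consumption_exponential(N, M)$value, 3)
  # the validity floor drops late points with a warning
  M2 <- c(M[1:6], 8, 5)
  expect_warning(est <- estimate_consumption_exponential(N, M2), "10")
  expect_equal(est$diagnostics$n_points, 6)
  expect_error(suppressWarnings(
    estimate_consumption_exponential(N, rep(5, 8))), "floor")
  # noiseless exponential simulation
  t <- seq(0, 6, 0.5)
  Nt <- 1e6 * exp(0.45 * t)
  Mt <- 100 - 5.4 * (Nt - 1e6) * 1e-6
  keep <- Mt >= 10
  expect_equal(estimate_consumption_exponential(Nt[keep], Mt[keep])$value,
               5.4, tolerance = 0.005)

  # saturation yields
  conc <- c(2, 5, 10, 15, 20, 25)
  dens <- conc / 2 * 1e6
  expect_equal(estimate_consumption_saturation(conc, dens)$value, 2)
  set.seed(5)
  noisy <- dens * exp(rnorm(6, 0, sqrt(log(1 + 0.05^2))))
  expect_equal(estimate_consumption_saturation(conc, noisy)$value, 2,
               tolerance = 0.05)
  expect_error(estimate_consumption_saturation(c(5, 5), c(1e6, 1.1e6)),
               "distinct")
})

test_that("release upper bound and batch death rate follow their formulas", {
  expect_equal(release_rate_upper_bound(0.1, 0.47, 1.5e7),
               0.47 * 0.1 / 1.5e7 * 1e6)
  expect_equal(signif(release_rate_upper_bound(0.1, 0.47, 1.5e7), 1), 0.003)
  expect_equal(release_rate_upper_bound(0, 0.47, 1.5e7), 0)
  expect_equal(release_rate_upper_bound(0.2, 0.47, 1.5e7),
               2 * release_rate_upper_bound(0.1, 0.47, 1.5e7))
  expect_error(release_rate_upper_bound(0.1, 0, 1e7), "> 0")

  expect_equal(batch_death_rate(0, 0.5), 0)
  expect_equal(batch_death_rate(0.001, 0.47), 4.7e-4)
  expect_error(batch_death_rate(0.1, 0), "> 0")
  # birth-death simulation: dead/live ratio converges to d/(b - d)
  b <- 0.5; d <- 0.005
  t <- seq(0, 30, 0.1)
  live <- 1e4 * exp((b - d) * t)
  dead <- d / (b - d) * (live - 1e4)
  ratio <- dead[length(t)] / live[length(t)]
  expect_equal(batch_death_rate(ratio, b - d), d, tolerance = 0.02)
})

test_that("full-loop recovery holds for randomized phenotypes", {
  set.seed(21)
  for (i in 1:4) {
    r <- runif(1, 0.1, 1)
    d <- runif(1, 0.001, 0.02)
    cc <- runif(1, 2, 6)
    s <- strain_phenotype(moser_params(0.5, 2, 2.5), death = d,
                          consumption = cc, release = r)
    cfg <- chemostat_config(supply_conc = 20, doubling = 8)
    ser <- simulate_chemostat(s, cfg, t_end = 96, times = seq(0, 96, 1))
    ss <- chemostat_steady_state(ser)
    expect_equal(estimate_consumption_ss(20, cfg$dil, ss$limiting,
                                         cfg$dil + d, ss$live)$exact,
                 cc, tolerance = 0.02)
    expect_equal(estimate_release_regression(ser, cfg$dil)$value, r,
                 tolerance = 0.02)
    expect_equal(estimate_death_regression(ser, cfg$dil)$value, d,
                 tolerance = 0.02)
  }
})
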