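tbl <- list(d_A = 0.015, d_L = 0.0024, r_A = 0.27, c_A = 3.1, c_L = 5.4)

test_that("exact and approximate closed forms evaluate correctly", {
  # deaths vanish
  expect_equal(gcomm_exact(0, 0, 0.3, 0.6, 2, 3), sqrt(0.3 * 0.6 / 6))
  # zero release: community decays at the slower death rate
  expect_equal(gcomm_exact(0.02, 0.005, 0, 0.5, 2, 3), -0.005)
  expect_equal(gcomm_exact(0.02, 0.005, 0.5, 0, 2, 3), -0.005)
  # published chemostat parameters with the 7-h release rate
  expect_equal(gcomm_exact(tbl$d_A, tbl$d_L, tbl$r_A, 0.78, tbl$c_A, tbl$c_L),
               0.1036, tolerance = 1e-3)
  expect_equal(gcomm_approx(tbl$d_A, tbl$d_L, tbl$r_A, 0.78, tbl$c_A, tbl$c_L),
               0.1035, tolerance = 1e-3)
  # equal deaths: forms coincide; unit check
  expect_equal(gcomm_exact(0.01, 0.01, 0.4, 0.4, 2, 2),
               gcomm_approx(0.01, 0.01, 0.4, 0.4, 2, 2))
  expect_equal(gcomm_approx(0, 0, 1, 1, 1, 1), 1)
  expect_error(gcomm_exact(0, 0, 1, 1, 0, 1), "> 0")
})

test_that("exact >= approximate, with equality iff death rates match", {
  set.seed(11)
  for (i in 1:50) {
    dA <- runif(1, 0, 0.05); dL <- runif(1, 0, 0.05)
    rA <- runif(1, 0.05, 1); rL <- runif(1, 0.05, 1)
    cA <- runif(1, 1, 8); cL <- runif(1, 1, 8)
    ge <- gcomm_exact(dA, dL, rA, rL, cA, cL)
    ga <- gcomm_approx(dA, dL, rA, rL, cA, cL)
    expect_gte(ge, ga)
    # the stated bound on the gap
    expect_lte(ge - ga, (dA - dL)^2 / (8 * sqrt(rA * rL / (cA * cL))))
  }
})

test_that("the variable-release quadratic reproduces the published prediction", {
  q <- gcomm_variable_release(tbl$d_A, tbl$d_L, tbl$r_A, tbl$c_A, tbl$c_L,
                              cosmo_linear_release_law())
  expect_equal(round(q$g_comm, 2), 0.10)
  expect_equal(q$linear_coef, 0.200, tolerance = 0.0075)
  expect_equal(q$constant_coef, -0.030, tolerance = 0.01)
  # degenerate law = fixed release
  flat <- release_law_linear(0.78, 0)
  q0 <- gcomm_variable_release(tbl$d_A, tbl$d_L, tbl$r_A, tbl$c_A, tbl$c_L,
                               flat)
  expect_equal(q0$g_comm,
               gcomm_approx(tbl$d_A, tbl$d_L, tbl$r_A, 0.78, tbl$c_A,
                            tbl$c_L))
  # unsustainable community
  expect_error(gcomm_variable_release(0.5, 0.5, 1e-6, 5, 5,
                                      release_law_linear(1e-5, -1)),
               "cannot sustain")
})

test_that("the variable-release root moves the right way with each parameter", {
  base <- gcomm_variable_release(tbl$d_A, tbl$d_L, tbl$r_A, tbl$c_A, tbl$c_L,
                                 cosmo_linear_release_law())$g_comm
  up <- function(...) gcomm_variable_release(...)$g_comm
  law <- cosmo_linear_release_law()
  expect_gt(up(tbl$d_A, tbl$d_L, tbl$r_A * 1.2, tbl$c_A, tbl$c_L, law), base)
  expect_gt(up(tbl$d_A, tbl$d_L, tbl$r_A, tbl$c_A, tbl$c_L,
               release_law_linear(law$intercept * 1.2, law$slope)), base)
  expect_lt(up(tbl$d_A * 2, tbl$d_L, tbl$r_A, tbl$c_A, tbl$c_L, law), base)
  expect_lt(up(tbl$d_A, tbl$d_L * 5, tbl$r_A, tbl$c_A, tbl$c_L, law), base)
  expect_lt(up(tbl$d_A, tbl$d_L, tbl$r_A, tbl$c_A * 1.3, tbl$c_L, law), base)
  expect_lt(up(tbl$d_A, tbl$d_L, tbl$r_A, tbl$c_A, tbl$c_L * 1.3, law), base)
})

test_that("doubling time inverts the growth rate", {
  expect_equal(doubling_time(log(2)), 1)
  expect_equal(doubling_time(0.10), 6.9, tolerance = 0.01)
  expect_equal(doubling_time(0.087), 8.0, tolerance = 0.005)
  expect_error(doubling_time(0), "> 0")
})

test_that("analytic partials agree with central finite differences", {
  f <- function(v) gcomm_approx(v[1], v[2], v[3], v[4], v[5], v[6])
  set.seed(3)
  for (i in 1:20) {
    v <- c(runif(2, 0.001, 0.05), runif(2, 0.05, 1), runif(2, 1, 8))
    p <- gcomm_partials(v[1], v[2], v[3], v[4], v[5], v[6])
    for (j in 1:6) {
      h <- 1e-6 * v[j]
      vp <- v; vp[j] <- v[j] + h
      vm <- v; vm[j] <- v[j] - h
      fd <- (f(vp) - f(vm)) / (2 * h)
      expect_equal(unname(p[j]), fd, tolerance = 1e-4)
    }
  }
})

test_that("error propagation reproduces the published terms and total", {
  pe <- propagate_error()
  expect_s3_class(pe, "growth_prediction")
  expect_equal(pe$terms[["r_A"]], 4.3e-6, tolerance = 0.01)
  expect_equal(pe$terms[["r_L"]], 8.3e-6, tolerance = 0.02)
  expect_equal(pe$terms[["d_A"]], 6e-8, tolerance = 0.05)
  expect_equal(pe$terms[["d_L"]], 2e-8, tolerance = 0.15)
  # the printed consumption terms back-compute to slightly different SEMs
  # than the rounded registry bounds imply; the comparison is relaxed
  expect_equal(pe$terms[["c_A"]], 1.3e-6, tolerance = 0.4)
  expect_equal(pe$terms[["c_L"]], 1.8e-6, tolerance = 0.4)
  expect_equal(round(pe$sem, 3), 0.004)
  expect_equal(pe$ci95_half, 2 * pe$sem)
  expect_equal(sum(pe$terms), pe$sem^2)
  expect_equal(pe$doubling_time_h, log(2) / pe$g_comm)
  # zero uncertainty propagates to zero
  z <- propagate_error(sems = setNames(rep(0, 6),
                                       c("d_A", "d_L", "r_A", "r_L",
                                         "c_A", "c_L")))
  expect_equal(z$sem, 0)
  expect_error(propagate_error(sems = setNames(c(-1, rep(0, 5)),
                                               names(z$terms))), ">= 0")
})

test_that("propagated sem matches a Monte-Carlo draw of the closed form", {
  inputs <- default_gcomm_inputs()
  v <- inputs$values; s <- inputs$sems
  set.seed(123)
  n <- 50000
  draw <- function(nm) rnorm(n, v[[nm]], s[[nm]])
  g_mc <- -(draw("d_A") + draw("d_L")) / 2 +
    sqrt(draw("r_A") * draw("r_L") / (draw("c_A") * draw("c_L")))
  expect_equal(sd(g_mc), propagate_error(v, s)$sem, tolerance = 0.05)
})
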