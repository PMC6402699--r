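# Single-strain chemostat model and the phenotype estimators built on it.
#
# In a chemostat, fresh medium with the limiting metabolite at concentration
# S0 is pumped in at a dilution rate dil while culture exits at the same
# rate. Live cells: dN/dt = (b(S) - d - dil) N; dead: d N - dil dead;
# limiting metabolite: (S0 - S) dil - c b(S) N 1e-6; released metabolite:
# r N 1e-6 - dil M (live release) or r_d d N 1e-6 - dil M (release upon
# death). At steady state b - d = dil.

#' Chemostat flow and dilution rate from a target doubling time
#'
#' @param volume culturing-vessel volume (mL), > 0.
#' @param doubling target doubling time (h), > 0 (Inf gives zero flow).
#' @return a list with `flow_ml_h` (= volume * ln(2) / doubling) and
#'   `dil_per_h` (= ln(2) / doubling).
#' @examples
#' dilution_rate_from_doubling(19, 8) # 1.646 mL/h
#' @export
dilution_rate_from_doubling <- function(volume, doubling) {
  if (volume <= 0 || doubling <= 0)
    stop("'volume' and 'doubling' must be > 0")
  list(flow_ml_h = volume * log(2) / doubling, dil_per_h = log(2) / doubling)
}

#' Chemostat configuration
#'
#' @param volume vessel volume (mL).
#' @param supply_conc reservoir concentration of the limiting metabolite
#'   (uM), >= 0.
#' @param dil dilution rate (per h); alternatively give `doubling` (h) and
#'   `dil` is derived as ln(2)/doubling.
#' @param doubling target doubling time (h), used when `dil` is NULL.
#' @param release_mode `"live"` (per live cell per hour) or `"dead"`
#'   (a fixed amount per cell death).
#' @param dead_release_amount fmole released per death (dead mode only).
#' @param init optional named list overriding initial state components
#'   `live`, `dead`, `limiting`, `released`. The defaults mirror the standard
#'   inoculation protocol: live at 1/3 of the expected steady-state density
#'   (reservoir concentration divided by consumption per birth), no dead
#'   cells, limiting metabolite at 60% of the reservoir concentration, no
#'   released metabolite.
#' @return an object of class `chemostat_config`.
#' @export
chemostat_config <- function(volume = 19, supply_conc = 20, dil = NULL,
                             doubling = NULL,
                             release_mode = c("live", "dead"),
                             dead_release_amount = NULL, init = NULL) {
  release_mode <- match.arg(release_mode)
  if (is.null(dil)) {
    if (is.null(doubling)) stop("give either 'dil' or 'doubling'")
    dil <- dilution_rate_from_doubling(volume, doubling)$dil_per_h
  }
  if (volume <= 0) stop("'volume' must be > 0")
  if (dil <= 0) stop("dilution rate must be > 0")
  if (supply_conc < 0) stop("'supply_conc' must be >= 0")
  if (release_mode == "dead" && is.null(dead_release_amount))
    stop("dead release mode requires 'dead_release_amount'")
  structure(list(volume = volume, supply_conc = supply_conc, dil = dil,
                 release_mode = release_mode,
                 dead_release_amount = dead_release_amount, init = init),
            class = "chemostat_config")
}

#' Simulate a single-strain chemostat
#'
#' Integrates the live/dead/limiting/released system described above with
#' `deSolve::ode()` (lsoda, rtol 1e-8). If the strain's release is a
#' [release_law_linear()] it is evaluated at the instantaneous net growth
#' rate `b(S) - d`; a [release_law_table()] is evaluated at the current
#' limiting-metabolite concentration.
#'
#' @param strain a [strain_phenotype()].
#' @param cfg a [chemostat_config()].
#' @param t_end end time (h).
#' @param times output times (h); default every 0.5 h.
#' @param rtol,atol solver tolerances.
#' @return a data frame of class `chemostat_series` with columns `time_h`,
#'   `live_per_ml`, `dead_per_ml`, `limiting_uM`, `released_uM`; the config
#'   is attached as attribute `config`.
#' @export
simulate_chemostat <- function(strain, cfg, t_end, times = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(strain, "strain_phenotype"),
            inherits(cfg, "chemostat_config"))
  if (t_end <= 0) stop("'t_end' must be > 0")
  expected_ss <- cfg$supply_conc / FMOLE_PER_ML_TO_UM / strain$consumption
  init <- cfg$init %||% list()
  y0 <- c(live = init$live %||% (expected_ss / 3),
          dead = init$dead %||% 0,
          S = init$limiting %||% (0.6 * cfg$supply_conc),
          M = init$released %||% 0)
  if (any(unlist(y0) < 0)) stop("initial state must be non-negative")
  if (is.null(times)) times <- seq(0, t_end, by = min(0.5, t_end / 50))

  derivs <- function(t, y, parms) {
    S <- max(y[["S"]], 0)
    b <- moser_birth_rate(S, strain$birth)
    d <- strain$death
    live <- y[["live"]]
    dM_release <- if (cfg$release_mode == "live") {
      r <- strain_release_rate(strain, b - d, S)
      r * live * FMOLE_PER_ML_TO_UM
    } else {
      cfg$dead_release_amount * d * live * FMOLE_PER_ML_TO_UM
    }
    list(c(
      live = (b - d - cfg$dil) * live,
      dead = d * live - cfg$dil * y[["dead"]],
      S = (cfg$supply_conc - S) * cfg$dil -
        strain$consumption * b * live * FMOLE_PER_ML_TO_UM,
      M = dM_release - cfg$dil * y[["M"]]
    ))
  }
  out <- deSolve::ode(unlist(y0), times, derivs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (any(!is.finite(out))) stop("chemostat solver failure")
  ser <- data.frame(time_h = out[, "time"], live_per_ml = out[, "live"],
                    dead_per_ml = out[, "dead"], limiting_uM = out[, "S"],
                    released_uM = out[, "M"])
  class(ser) <- c("chemostat_series", "data.frame")
  attr(ser, "config") <- cfg
  attr(ser, "strain") <- strain
  ser
}

#' Steady-state summary of a chemostat series
#'
#' Detects settling as the first sampling interval over which the live
#' density changes by less than `settle_tol` (relative), then averages over
#' the final `final_frac` of the settled portion.
#'
#' @param series a `chemostat_series`.
#' @param settle_tol relative per-interval change treated as settled.
#' @param final_frac fraction of the settled portion averaged.
#' @return a list of means `live`, `dead`, `limiting`, `released` and the
#'   averaged row indices `window`.
#' @export
chemostat_steady_state <- function(series, settle_tol = 0.05,
                                   final_frac = 1 / 3) {
  n <- nrow(series)
  rel <- abs(diff(series$live_per_ml)) / pmax(series$live_per_ml[-n], 1e-300)
  settled <- which(rel < settle_tol)
  i0 <- if (length(settled)) settled[1L] + 1L else 1L
  idx <- seq.int(n - floor((n - i0) * final_frac), n)
  list(live = mean(series$live_per_ml[idx]),
       dead = mean(series$dead_per_ml[idx]),
       limiting = mean(series$limiting_uM[idx]),
       released = mean(series$released_uM[idx]),
       window = idx)
}

## ---- steady-state estimators -------------------------------------------

#' Consumption per birth from chemostat steady state
#'
#' At steady state the limiting-metabolite balance gives
#' `c = (S0 - S_ss) dil / (b * live_ss)` (exact) which reduces to
#' `c = S0 / live_ss` when `S_ss << S0` and `b ~ dil` (approximate), with
#' uM-to-fmole/mL conversion.
#'
#' @param supply_conc reservoir concentration S0 (uM).
#' @param dil dilution rate (per h).
#' @param limiting_ss steady-state limiting-metabolite concentration (uM).
#' @param b steady-state birth rate (per h); at steady state `b = dil + d`.
#' @param live_ss steady-state live density (cells/mL), > 0.
#' @return a list with `exact` and `approx` consumption (fmole/cell).
#' @export
estimate_consumption_ss <- function(supply_conc, dil, limiting_ss, b,
                                    live_ss) {
  if (live_ss <= 0) stop("live density must be > 0")
  list(
    exact = (supply_conc - limiting_ss) * dil / (b * live_ss) /
      FMOLE_PER_ML_TO_UM,
    approx = supply_conc / live_ss / FMOLE_PER_ML_TO_UM
  )
}

#' Death rate from chemostat steady state
#'
#' From the dead-cell balance, `d = dil * dead_ss / live_ss`.
#'
#' @param dil dilution rate (per h).
#' @param dead_ss,live_ss steady-state dead and live densities (cells/mL);
#'   `live_ss > 0`.
#' @return death rate (per h).
#' @export
estimate_death_ss <- function(dil, dead_ss, live_ss) {
  if (live_ss <= 0) stop("live density must be > 0")
  dil * dead_ss / live_ss
}

#' Release rate from chemostat steady state
#'
#' From the released-metabolite balance, `r = dil * M_ss / live_ss`, with
#' uM-to-fmole/mL conversion.
#'
#' @param dil dilution rate (per h).
#' @param released_ss steady-state released-metabolite concentration (uM).
#' @param live_ss steady-state live density (cells/mL), > 0.
#' @return release rate (fmole/cell/h).
#' @export
estimate_release_ss <- function(dil, released_ss, live_ss) {
  if (live_ss <= 0) stop("live density must be > 0")
  dil * released_ss / live_ss / FMOLE_PER_ML_TO_UM
}

## ---- regression estimators ---------------------------------------------

#' Exponentially weighted running trapezoid integral
#'
#' Computes `int_0^t f(tau) exp(dil * tau) dtau` on the sampling grid by the
#' composite trapezoid rule: the integral at `t + dt` is the integral at `t`
#' plus `dt * (g(t) + g(t + dt)) / 2` for the weighted integrand `g`; the
#' value at the first time point is 0.
#'
#' @param times sample times (h), strictly increasing, >= 2 points.
#' @param f sampled values.
#' @param dil exponential weight rate (per h); 0 gives the plain running
#'   integral.
#' @return vector of running integrals, same length as `times`.
#' @examples
#' exp_weighted_integral(c(0, 1, 2), c(0, 1, 2), 0) # 0, 0.5, 2
#' @export
exp_weighted_integral <- function(times, f, dil = 0) {
  if (length(times) < 2L) stop("need at least 2 points")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  g <- f * exp(dil * times)
  n <- length(g)
  c(0, cumsum(diff(times) * (g[-1L] + g[-n]) / 2))
}

#' Release rate by regression over the whole chemostat time course
#'
#' If release is constant, `M exp(dil t) = r * int_0^t live exp(dil tau)
#' dtau`, so regressing the weighted released-metabolite concentration
#' (converted to fmole/mL) on the weighted live-density integral, through the
#' origin, estimates the release rate as the slope. Uses both pre-steady-state
#' and steady-state data; requires the released metabolite to start at 0 (or
#' be baseline-subtracted).
#'
#' @param series a `chemostat_series` (or data frame with `time_h`,
#'   `live_per_ml`, `released_uM`).
#' @param dil dilution rate (per h).
#' @return a `cosmor_estimate` (fmole/cell/h) with regression diagnostics.
#' @export
estimate_release_regression <- function(series, dil) {
  if (nrow(series) < 3L) stop("need at least 3 points")
  x <- exp_weighted_integral(series$time_h, series$live_per_ml, dil)
  y <- series$released_uM / FMOLE_PER_ML_TO_UM * exp(dil * series$time_h)
  fit <- stats::lm(y ~ 0 + x)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  new_estimate(unname(coef(fit)[1L]), sm$coefficients[1L, 2L],
               "release regression (through origin)",
               diagnostics = list(r_squared = 1 - sum(fit$residuals^2) /
                                    sum(y^2)))
}

#' Death rate by regression over the whole chemostat time course
#'
#' If the death rate is constant, `dead exp(dil t) = dead(0) + d *
#' int_0^t live exp(dil tau) dtau`; the slope of the free-intercept
#' regression estimates the death rate.
#'
#' @inheritParams estimate_release_regression
#' @return a `cosmor_estimate` (per h); the fitted intercept (initial dead
#'   density) is reported in `diagnostics`.
#' @export
estimate_death_regression <- function(series, dil) {
  if (nrow(series) < 3L) stop("need at least 3 points")
  x <- exp_weighted_integral(series$time_h, series$live_per_ml, dil)
  y <- series$dead_per_ml * exp(dil * series$time_h)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  new_estimate(unname(coef(fit)[2L]), sm$coefficients[2L, 2L],
               "death regression (free intercept)",
               diagnostics = list(intercept = unname(coef(fit)[1L]),
                                  r_squared = sm$r.squared))
}

## ---- live versus dead release ------------------------------------------

#' Discriminate live-cell from death-triggered release in starvation data
#'
#' Under live release at a constant per-cell rate the metabolite scales
#' linearly, through the origin, with the live density integrated over time
#' (slope = fmole/cell/h). Under release upon death it scales linearly with
#' the dead density (slope = fmole per death; free intercept, since the
#' initial dead pool released nothing into the assay medium). Both fits are
#' reported with an R^2 linearity metric (computed about zero for the
#' origin-constrained live model) and the better-supported mode is flagged;
#' R^2 differences below `tie_tol` are reported as `"indeterminate"` — in
#' particular, series whose dead density is exactly proportional to the
#' integrated live density (constant death rate, no dilution, no initial
#' dead pool) cannot distinguish the modes. A constant regressor makes that
#' model inapplicable.
#'
#' @param times sample times (h).
#' @param live,dead live and dead densities (cells/mL).
#' @param metabolite released-metabolite concentration (uM), starting at 0.
#' @param dil dilution rate (per h); 0 for starvation data. With `dil > 0`
#'   the comparison is made on dilution-corrected variables (each series
#'   weighted by `exp(dil * t)`, the live integral exponentially weighted);
#'   chemostat data with a constant death rate then correctly reads as
#'   indeterminate, reflecting the mathematical equivalence of live release
#'   and death-triggered release at rate-matched parameters.
#' @param tie_tol R^2 difference below which the comparison is flagged
#'   indeterminate.
#' @return a list of class `release_mode_comparison`: per-model slope, sem
#'   and R^2 (`live`, `dead`), residuals for inspection, and `preferred`
#'   (`"live"`, `"dead"` or `"indeterminate"`).
#' @export
compare_release_models <- function(times, live, dead, metabolite, dil = 0,
                                   tie_tol = 0.02) {
  if (length(times) < 4L) stop("need at least 4 points")
  w <- exp(dil * times)
  y <- metabolite / FMOLE_PER_ML_TO_UM * w
  dead <- dead * w
  x_live <- exp_weighted_integral(times, live, dil)
  fit_one <- function(x, through_origin) {
    if (stats::sd(x) == 0 || all(x == 0))
      return(list(slope = NA_real_, sem = NA_real_, r_squared = NA_real_,
                  residuals = NULL, applicable = FALSE))
    fit <- if (through_origin) stats::lm(y ~ 0 + x) else stats::lm(y ~ x)
    sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
    k <- if (through_origin) 1L else 2L
    r2 <- if (through_origin) 1 - sum(fit$residuals^2) / sum(y^2)
          else sm$r.squared
    list(slope = unname(coef(fit)[k]), sem = sm$coefficients[k, 2L],
         r_squared = r2, residuals = unname(fit$residuals),
         applicable = TRUE)
  }
  live_model <- fit_one(x_live, through_origin = TRUE)
  dead_model <- fit_one(dead, through_origin = FALSE)
  preferred <- if (!live_model$applicable && !dead_model$applicable) {
    "indeterminate"
  } else if (!dead_model$applicable) {
    "live"
  } else if (!live_model$applicable) {
    "dead"
  } else if (abs(live_model$r_squared - dead_model$r_squared) < tie_tol) {
    "indeterminate"
  } else if (live_model$r_squared > dead_model$r_squared) "live" else "dead"
  structure(list(live = live_model, dead = dead_model, preferred = preferred),
            class = "release_mode_comparison")
}

#' @export
print.release_mode_comparison <- function(x, ...) {
  cat(sprintf("Release-mode comparison: preferred = %s\n", x$preferred))
  cat(sprintf("  live model:  slope %.4g fmole/cell/h, R^2 %.4f\n",
              x$live$slope, x$live$r_squared))
  cat(sprintf("  dead model:  slope %.4g fmole/death,  R^2 %.4f\n",
              x$dead$slope, x$dead$r_squared))
  invisible(x)
}

#' Plausibility arithmetic for death-triggered release
#'
#' `dead_release_conc()` (forward): the supernatant concentration that a
#' per-cell content would produce if every dead cell released it,
#' `content * dead_density * 1e-6` uM. `dead_release_required()` (inverse):
#' the per-cell amount each dead cell would need to release to account for an
#' observed concentration, `M / (dead_density * 1e-6)` fmole/cell.
#'
#' @param content per-cell metabolite content (fmole/cell).
#' @param dead_density dead-cell density (cells/mL); must be > 0 for the
#'   inverse form.
#' @param M observed supernatant concentration (uM).
#' @return concentration in uM (forward) or fmole/cell (inverse).
#' @examples
#' dead_release_conc(0.12, 1e5)    # 0.012 uM
#' dead_release_required(10, 1e5)  # 100 fmole/cell
#' @export
dead_release_conc <- function(content, dead_density) {
  content * dead_density * FMOLE_PER_ML_TO_UM
}

#' @rdname dead_release_conc
#' @export
dead_release_required <- function(M, dead_density) {
  if (any(dead_density <= 0)) stop("dead density must be > 0")
  M / (dead_density * FMOLE_PER_ML_TO_UM)
}

## ---- batch-culture estimators ------------------------------------------

#' Consumption per birth in an exponential batch culture
#'
#' In excess metabolite, `M(t) - M(0) = -c (N(t) - N(0))`, so the slope of
#' metabolite concentration against cell density is `-c` (unit-converted).
#' Time points after the metabolite has fallen below `floor_uM` are
#' disregarded (the assay is unreliable there even though growth continues).
#'
#' @param N cell densities (cells/mL).
#' @param M metabolite concentrations (uM), same order as `N` (time order).
#' @param floor_uM validity floor (uM).
#' @return a `cosmor_estimate` (fmole/cell).
#' @export
estimate_consumption_exponential <- function(N, M, floor_uM = 10) {
  stopifnot(length(N) == length(M))
  low <- which(M < floor_uM)
  if (length(low)) {
    keep <- seq_len(min(low) - 1L)
    if (length(keep) < 2L)
      stop(sprintf("all usable points below the %g uM validity floor",
                   floor_uM))
    warning(sprintf("%d point(s) after M < %g uM disregarded",
                    length(N) - length(keep), floor_uM))
    N <- N[keep]
    M <- M[keep]
  }
  fit <- stats::lm(M ~ N)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  new_estimate(-unname(coef(fit)[2L]) / FMOLE_PER_ML_TO_UM,
               sm$coefficients[2L, 2L] / FMOLE_PER_ML_TO_UM,
               "exponential-batch consumption",
               diagnostics = list(r_squared = sm$r.squared,
                                  n_points = length(N)))
}

#' Consumption per birth from saturated batch yields
#'
#' Final total density regressed through the origin on the input
#' concentration of the limiting metabolite; consumption per birth is
#' 1/slope (unit-converted).
#'
#' @param conc input concentrations (uM), >= 2 distinct levels.
#' @param density final total densities (cells/mL).
#' @return a `cosmor_estimate` (fmole/cell; sem by the delta method).
#' @export
estimate_consumption_saturation <- function(conc, density) {
  stopifnot(length(conc) == length(density))
  if (length(unique(conc)) < 2L)
    stop("need at least 2 distinct concentration levels")
  fit <- stats::lm(density ~ 0 + conc)
  slope <- unname(coef(fit)[1L])
  if (slope <= 0) stop("non-positive yield slope")
  se <- suppressWarnings(summary(fit))$coefficients[1L, 2L]
  new_estimate(1 / slope / FMOLE_PER_ML_TO_UM,
               se / slope^2 / FMOLE_PER_ML_TO_UM,
               "saturation-yield consumption",
               diagnostics = list(slope = slope))
}

#' Upper bound on the release rate of an exponentially growing culture
#'
#' For exponential growth at rate `g`, the released metabolite obeys
#' `M(T) ~ (r/g) N(T)` once `N(T) >> N(0)`, so `r = g M(T) / N(T)`
#' (unit-converted). Used with the assay's detection limit as `M(T)` this
#' bounds a sub-detection release rate from above.
#'
#' @param M_T supernatant concentration, or assay detection limit (uM).
#' @param g growth rate (per h), > 0.
#' @param N_T population density at time T (cells/mL), > 0.
#' @return release-rate bound (fmole/cell/h).
#' @examples
#' release_rate_upper_bound(0.1, 0.47, 1.5e7) # ~0.003
#' @export
release_rate_upper_bound <- function(M_T, g, N_T) {
  if (g <= 0) stop("growth rate must be > 0")
  if (N_T <= 0) stop("density must be > 0")
  g * M_T / N_T / FMOLE_PER_ML_TO_UM
}

#' Death rate in a non-limited exponential batch culture
#'
#' For exponential birth-death dynamics the dead/live ratio converges to
#' `d / (b - d)`, so `d = g * dead_live_ratio` with `g` the net growth rate.
#'
#' @param dead_live_ratio ratio of dead to live cell densities.
#' @param g net growth rate (per h), > 0.
#' @return death rate (per h).
#' @export
batch_death_rate <- function(dead_live_ratio, g) {
  if (g <= 0) stop("net growth rate must be > 0")
  g * dead_live_ratio
}
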