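# Well-mixed two-strain community ODE model and growth-rate extraction.

#' Moser birth rate
#'
#' `b(s) = b_max * s^n / (s^n + K^n)`: saturating birth kinetics with
#' cooperativity `n` on the limiting metabolite concentration `s`.
#'
#' @param s metabolite concentration(s), uM, >= 0 (callers must clamp
#'   transient numerical undershoots before calling).
#' @param p a [moser_params()] object.
#' @return birth rate(s) in per h, between 0 and `b_max` and non-decreasing
#'   in `s`.
#' @examples
#' moser_birth_rate(2.1, moser_params(0.51, 2.1, 3.2)) # b_max / 2
#' @export
moser_birth_rate <- function(s, p) {
  stopifnot(inherits(p, "moser_params"))
  if (any(s < 0)) stop("metabolite concentration must be >= 0")
  sn <- s^p$n
  p$b_max * sn / (sn + p$K^p$n)
}

# Release rate of one strain given its current net growth rate and the
# concentration of the metabolite it consumes.
strain_release_rate <- function(phen, g, s_own) {
  if (is.numeric(phen$release)) return(phen$release)
  if (phen$release$type == "linear") release_rate(phen$release, g = g)
  else release_rate(phen$release, H = s_own)
}

#' Simulate the well-mixed community
#'
#' Integrates the four-variable community model: each live population grows at
#' a Moser birth rate on the partner-supplied metabolite and dies at a fixed
#' rate; each metabolite is produced by its releaser and consumed
#' proportionally to the consumer's births,
#' \deqn{dN_L/dt = (b_L(L) - d_L) N_L, \quad
#'       dL/dt = r_L N_A 10^{-6} - c_L b_L(L) N_L 10^{-6},}
#' and symmetrically for the partner. Dead populations are tracked as
#' by-products (`d * N`). If the lysine release of the A-L+ strain is a
#' [release_law_linear()] it is evaluated at that strain's instantaneous net
#' growth rate `b_A(A) - d_A`; if a [release_law_table()], at the current
#' hypoxanthine concentration.
#'
#' Integration uses `deSolve::ode()` (lsoda, stiff-capable) with relative
#' tolerance `1e-8`; metabolite arguments of the birth law are clamped at 0 to
#' guard against transient numerical undershoot.
#'
#' @param phenotypes list with `LA` and `AL` [strain_phenotype()] objects (as
#'   returned by [registry_phenotypes()]).
#' @param init named numeric vector with `NL_per_ml`, `NA_per_ml`, `L_uM`,
#'   `A_uM` (optionally `deadL_per_ml`, `deadA_per_ml`), all >= 0. The default
#'   is the standard community inoculation: 1:1 strain ratio at 1e5 cells/mL
#'   total with no free metabolite.
#' @param t_end end time (h), > 0.
#' @param times output times; default 401 equally spaced points.
#' @param rtol,atol solver tolerances.
#' @return a data frame of class `cosmo_trajectory` with columns `time_h`,
#'   `NL_per_ml`, `NA_per_ml`, `L_uM`, `A_uM`, `deadL_per_ml`, `deadA_per_ml`.
#' @export
simulate_wellmixed <- function(phenotypes,
                               init = c(NL_per_ml = 5e4, NA_per_ml = 5e4,
                                        L_uM = 0, A_uM = 0),
                               t_end, times = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(is.list(phenotypes), !is.null(phenotypes$LA),
            !is.null(phenotypes$AL))
  if (any(init < 0)) stop("initial state must be non-negative")
  if (t_end <= 0) stop("'t_end' must be > 0")
  pL <- phenotypes$LA
  pA <- phenotypes$AL
  y0 <- c(NL = unname(init["NL_per_ml"]), NAp = unname(init["NA_per_ml"]),
          L = unname(init["L_uM"]), A = unname(init["A_uM"]),
          deadL = unname(init["deadL_per_ml"] %na% 0),
          deadA = unname(init["deadA_per_ml"] %na% 0))
  if (is.null(times)) times <- seq(0, t_end, length.out = 401L)

  derivs <- function(t, y, parms) {
    L <- max(y[["L"]], 0)
    A <- max(y[["A"]], 0)
    bL <- moser_birth_rate(L, pL$birth)
    bA <- moser_birth_rate(A, pA$birth)
    rA <- strain_release_rate(pL, bL - pL$death, L)
    rL <- strain_release_rate(pA, bA - pA$death, A)
    NL <- y[["NL"]]
    NAp <- y[["NAp"]]
    list(c(
      NL = (bL - pL$death) * NL,
      NAp = (bA - pA$death) * NAp,
      L = (rL * NAp - pL$consumption * bL * NL) * FMOLE_PER_ML_TO_UM,
      A = (rA * NL - pA$consumption * bA * NAp) * FMOLE_PER_ML_TO_UM,
      deadL = pL$death * NL,
      deadA = pA$death * NAp
    ))
  }
  out <- deSolve::ode(y0, times, derivs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (any(!is.finite(out))) {
    last_ok <- max(which(apply(is.finite(out), 1, all)))
    stop(sprintf("solver failure at t = %g h (last valid state at t = %g h)",
                 out[last_ok + 1L, 1L], out[last_ok, 1L]))
  }
  traj <- data.frame(time_h = out[, "time"],
                     NL_per_ml = out[, "NL"], NA_per_ml = out[, "NAp"],
                     L_uM = out[, "L"], A_uM = out[, "A"],
                     deadL_per_ml = out[, "deadL"],
                     deadA_per_ml = out[, "deadA"])
  class(traj) <- c("cosmo_trajectory", "data.frame")
  attr(traj, "phenotypes") <- phenotypes
  traj
}

`%na%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Accumulative densities across dilution events
#'
#' Reconstructs the density a culture would have reached without dilutions:
#' each raw density at time `t` is multiplied by the product of all dilution
#' factors applied at or before `t` (raw densities recorded at an event time
#' are taken to be post-dilution).
#'
#' @param times sample times (h), non-decreasing.
#' @param densities numeric vector, or data frame/matrix of density columns,
#'   one row per time.
#' @param events data frame with columns `time` and `factor` (> 0); event
#'   times must lie within `range(times)`.
#' @return densities scaled to accumulative values, same shape as input.
#' @export
accumulate_densities <- function(times, densities, events = NULL) {
  if (is.null(events) || nrow(events) == 0L) return(densities)
  stopifnot(all(c("time", "factor") %in% names(events)))
  if (any(events$factor <= 0)) stop("dilution factors must be > 0")
  if (any(events$time < min(times) | events$time > max(times)))
    stop("dilution event outside the sampled time range")
  cumfac <- vapply(times, function(t) prod(events$factor[events$time <= t]),
                   numeric(1))
  # multiplying a matrix/data frame by a length-nrow vector scales row i of
  # every column by cumfac[i]
  densities * cumfac
}

#' Fit the steady-state exponential growth rate
#'
#' Ordinary least-squares slope of `ln(total density)` against time over a
#' selected window, with the slope's standard error.
#'
#' The window can be given explicitly (`t_min`/`t_max` in hours, or
#' `min_total`/`max_total` as density cutoffs — e.g. the 9e7-total-cell onset
#' cutoff or the 1e8 stationary-phase exclusion used for plate-grown
#' communities). If no constraint is supplied, a post-lag window is detected
#' automatically: instantaneous rates are computed between successive points
#' and the fit starts at the first point whose rate is within 5% of the
#' late-trajectory (median of the last fifth) rate. Intended for smooth
#' (simulated or lightly noisy) series; with noisy data give the window
#' explicitly.
#'
#' @param times sample times (h).
#' @param total total (accumulative) live density (cells/mL or total cells).
#' @param t_min,t_max time window bounds (h).
#' @param min_total,max_total density window bounds.
#' @return a `cosmor_estimate` (value = rate per h, sem = slope standard
#'   error) with the fit window and R^2 in `diagnostics`.
#' @export
fit_growth_rate <- function(times, total, t_min = NULL, t_max = NULL,
                            min_total = NULL, max_total = NULL) {
  stopifnot(length(times) == length(total))
  keep <- rep(TRUE, length(times))
  auto <- is.null(t_min) && is.null(t_max) && is.null(min_total) &&
    is.null(max_total)
  if (!is.null(t_min)) keep <- keep & times >= t_min
  if (!is.null(t_max)) keep <- keep & times <= t_max
  if (!is.null(min_total)) keep <- keep & total >= min_total
  if (!is.null(max_total)) keep <- keep & total <= max_total
  if (auto && length(times) >= 5L) {
    r <- diff(log(total)) / diff(times)
    r_ref <- stats::median(tail(r, max(3L, length(r) %/% 5L)))
    ok <- which(abs(r - r_ref) <= 0.05 * abs(r_ref))
    if (length(ok)) keep <- keep & seq_along(times) > min(ok) - 1L
  }
  t_sel <- times[keep]
  n_sel <- total[keep]
  if (length(t_sel) < 3L)
    stop("growth-rate window selects fewer than 3 points")
  fit <- stats::lm(log(n_sel) ~ t_sel)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  new_estimate(
    value = unname(coef(fit)[2L]),
    sem = sm$coefficients[2L, 2L],
    method = "log-linear OLS",
    diagnostics = list(intercept = unname(coef(fit)[1L]),
                       r_squared = sm$r.squared,
                       window = range(t_sel), n_points = length(t_sel))
  )
}

#' @rdname fit_growth_rate
#' @param traj a `cosmo_trajectory`.
#' @param events optional dilution events (see [accumulate_densities()]);
#'   applied before totalling.
#' @param ... passed to `fit_growth_rate()`.
#' @export
fit_growth_rate_trajectory <- function(traj, events = NULL, ...) {
  tot <- traj$NL_per_ml + traj$NA_per_ml
  if (!is.null(events))
    tot <- accumulate_densities(traj$time_h, tot, events)
  fit_growth_rate(traj$time_h, tot, ...)
}
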