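# Two-genotype (ancestor/mutant) dynamics: mutant generation at a per-birth
# conversion probability, batch accumulation, chemostat competition, and the
# back-of-envelope arithmetic for pre-existing mutants.

#' Ancestor/mutant parameter set
#'
#' The conversion rate `mu` ("per cell per generation", e.g. chromosomal
#' mis-segregation) is implemented as a per-birth probability: a fraction
#' `mu` of ancestor births yield mutant offspring, the only formulation
#' consistent with continuous-time birth dynamics.
#'
#' @param mu mutants generated per ancestor birth, in \[0, 1\].
#' @param b_anc,b_mut ancestor and mutant birth rates (per h) in the modelled
#'   environment, or [moser_params()] objects for concentration-dependent
#'   birth (chemostat competition).
#' @param d_anc,d_mut death rates (per h).
#' @param c_anc,c_mut consumption per birth (fmole/cell); needed for
#'   chemostat competition.
#' @param f0 initial mutant fraction, in \[0, 1\].
#' @return an object of class `evo_params`.
#' @export
evo_params <- function(mu, b_anc, b_mut, d_anc = 0, d_mut = 0,
                       c_anc = NULL, c_mut = NULL, f0 = 0) {
  if (mu < 0 || mu > 1) stop("'mu' must be in [0, 1]")
  if (f0 < 0 || f0 > 1) stop("'f0' must be in [0, 1]")
  structure(list(mu = mu, b_anc = b_anc, b_mut = b_mut, d_anc = d_anc,
                 d_mut = d_mut, c_anc = c_anc, c_mut = c_mut, f0 = f0),
            class = "evo_params")
}

#' Mutant accumulation during exponential batch growth
#'
#' After a lag of frozen composition, the genotypes follow
#' `dN_anc/dt = (1 - mu) b_anc N_anc` and
#' `dN_mut/dt = b_mut N_mut + mu b_anc N_anc`
#' (ancestor births route a fraction `mu` into the mutant pool, so total
#' births are conserved). Solved in closed form.
#'
#' @param p an [evo_params()] with scalar birth rates.
#' @param lag dead time (h) before exponential growth, composition frozen.
#' @param t_end end time (h).
#' @param times output times; default 201 equally spaced points.
#' @param N0 initial total density.
#' @return data frame with `time_h`, `N_anc`, `N_mut`, `mutant_fraction`.
#' @export
simulate_batch_mutant_dynamics <- function(p, lag = 0, t_end, times = NULL,
                                           N0 = 1e6) {
  stopifnot(inherits(p, "evo_params"), is.numeric(p$b_anc),
            is.numeric(p$b_mut))
  if (is.null(times)) times <- seq(0, t_end, length.out = 201L)
  na0 <- N0 * (1 - p$f0)
  nm0 <- N0 * p$f0
  a <- (1 - p$mu) * p$b_anc
  tg <- pmax(times - lag, 0)
  N_anc <- na0 * exp(a * tg)
  k <- p$mu * p$b_anc * na0
  N_mut <- if (abs(a - p$b_mut) > 1e-12) {
    q <- k / (a - p$b_mut)
    (nm0 - q) * exp(p$b_mut * tg) + q * exp(a * tg)
  } else {
    (nm0 + k * tg) * exp(a * tg)
  }
  data.frame(time_h = times, N_anc = N_anc, N_mut = N_mut,
             mutant_fraction = N_mut / (N_anc + N_mut))
}

#' Ancestor/mutant competition in a chemostat
#'
#' Two genotypes share one limiting metabolite in a chemostat; each has its
#' own Moser birth law, death rate and consumption per birth, and ancestor
#' births convert to mutants with probability `mu`:
#' `dN_anc/dt = ((1-mu) b_anc(S) - d_anc - dil) N_anc`,
#' `dN_mut/dt = (b_mut(S) - d_mut - dil) N_mut + mu b_anc(S) N_anc`.
#'
#' @param p an [evo_params()] whose `b_anc`/`b_mut` are [moser_params()] and
#'   whose `c_anc`/`c_mut` are set.
#' @param cfg a [chemostat_config()].
#' @param t_end end time (h).
#' @param init_total initial total density (cells/mL); split by `p$f0`.
#' @param times output times.
#' @param rtol solver tolerance.
#' @return data frame with `time_h`, `N_anc`, `N_mut`, `mutant_fraction`,
#'   `limiting_uM`.
#' @export
simulate_chemostat_competition <- function(p, cfg, t_end, init_total = 1e6,
                                           times = NULL, rtol = 1e-8) {
  stopifnot(inherits(p, "evo_params"), inherits(p$b_anc, "moser_params"),
            inherits(p$b_mut, "moser_params"),
            inherits(cfg, "chemostat_config"))
  if (is.null(p$c_anc) || is.null(p$c_mut))
    stop("chemostat competition requires 'c_anc' and 'c_mut'")
  if (is.null(times)) times <- seq(0, t_end, length.out = 201L)
  y0 <- c(anc = init_total * (1 - p$f0), mut = init_total * p$f0,
          S = (cfg$init %||% list())$limiting %||% (0.6 * cfg$supply_conc))
  derivs <- function(t, y, parms) {
    S <- max(y[["S"]], 0)
    ba <- moser_birth_rate(S, p$b_anc)
    bm <- moser_birth_rate(S, p$b_mut)
    anc <- y[["anc"]]
    mut <- y[["mut"]]
    list(c(
      anc = ((1 - p$mu) * ba - p$d_anc - cfg$dil) * anc,
      mut = (bm - p$d_mut - cfg$dil) * mut + p$mu * ba * anc,
      S = (cfg$supply_conc - S) * cfg$dil -
        (p$c_anc * ba * anc + p$c_mut * bm * mut) * FMOLE_PER_ML_TO_UM
    ))
  }
  out <- deSolve::ode(y0, times, derivs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = 1e-10)
  if (any(!is.finite(out))) stop("competition solver failure")
  data.frame(time_h = out[, "time"], N_anc = out[, "anc"],
             N_mut = out[, "mut"],
             mutant_fraction = out[, "mut"] / (out[, "anc"] + out[, "mut"]),
             limiting_uM = out[, "S"])
}

#' Fitness advantage from a mutant-fraction (or ratio) time course
#'
#' For two exponentially growing genotypes,
#' `ln(E(t)/A(t)) = ln(E(0)/A(0)) + (r_E - r_A) t`; the OLS slope of the
#' log-ratio against time is the fitness advantage.
#'
#' @param times sample times (h).
#' @param fractions mutant fractions, strictly inside (0, 1); converted to
#'   ratios `f/(1-f)`. Give either `fractions` or `ratios`.
#' @param ratios mutant/ancestor density ratios, > 0.
#' @return a `cosmor_estimate` (per h); sem is `NA` with only two points.
#' @examples
#' fitness_advantage_from_ratio(c(0, 5.7), fractions = c(0.04, 0.40))
#' @export
fitness_advantage_from_ratio <- function(times, fractions = NULL,
                                         ratios = NULL) {
  if (is.null(ratios)) {
    if (is.null(fractions)) stop("give 'fractions' or 'ratios'")
    if (any(fractions <= 0 | fractions >= 1))
      stop("fractions must be strictly inside (0, 1)")
    ratios <- fractions / (1 - fractions)
  }
  if (any(ratios <= 0)) stop("ratios must be > 0")
  if (length(times) < 2L) stop("need at least 2 points")
  fit <- stats::lm(log(ratios) ~ times)
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients[2L, 2L],
                 error = function(e) NA_real_)
  new_estimate(unname(coef(fit)[2L]), se, "log-ratio fitness slope",
               diagnostics = list(intercept = unname(coef(fit)[1L])))
}

#' Initial mutant frequency back-extrapolated from an observed frequency
#'
#' `f0 = f_obs / exp(fitness_diff * t)`: running the exponential ratio
#' dynamics backwards from the first observation.
#'
#' @param f_obs observed mutant frequency (> 0).
#' @param fitness_diff fitness advantage of the mutant (per h), >= 0.
#' @param t time since the start (h), >= 0.
#' @return inferred initial frequency.
#' @examples
#' initial_mutant_frequency(0.04, 0.4, 26.3) # ~1e-6
#' @export
initial_mutant_frequency <- function(f_obs, fitness_diff, t) {
  if (f_obs <= 0) stop("'f_obs' must be > 0")
  if (fitness_diff < 0 || t < 0) stop("'fitness_diff' and 't' must be >= 0")
  f_obs / exp(fitness_diff * t)
}

#' Expected number of pre-existing mutants in an inoculum
#'
#' A culture grown from a single cell to size `N` accumulates about
#' `2 N mu_p` mutants for a phenotypic mutation rate `mu_p` per cell per
#' generation: mutation opportunities total `1 + 2 + ... + 2^n ~ 2^{n+1}`,
#' i.e. twice the final population size.
#'
#' @param N_pop inoculum population size, > 0.
#' @param rate phenotypic mutation rate(s) per cell per generation, >= 0;
#'   may be a vector (e.g. a literature range).
#' @return expected count(s), `2 * N_pop * rate`.
#' @examples
#' expected_preexisting_mutants(8e7, c(0.5e-7, 30e-7)) # 8 and 480
#' @export
expected_preexisting_mutants <- function(N_pop, rate) {
  if (N_pop <= 0) stop("'N_pop' must be > 0")
  if (any(rate < 0)) stop("rates must be >= 0")
  2 * N_pop * rate
}
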