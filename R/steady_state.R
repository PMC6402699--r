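# Closed-form steady-state community growth rate and error propagation.
#
# At the community steady state both strains grow at the common rate g and
# metabolite concentrations are constant, which yields
#   r_A r_L = c_A c_L (g + d_L)(g + d_A).
# Solving the quadratic gives the exact form (gcomm_exact); dropping the
# (d_A - d_L)^2/4 term under the square root gives the standard
# approximation (gcomm_approx) used for error propagation.

check_gcomm_args <- function(d_A, d_L, r_A, r_L, c_A, c_L) {
  if (c_A <= 0 || c_L <= 0) stop("consumption per birth must be > 0")
  if (r_A < 0 || r_L < 0) stop("release rates must be >= 0")
  if (d_A < 0 || d_L < 0) stop("death rates must be >= 0")
}

#' Steady-state community growth rate (closed forms)
#'
#' `gcomm_exact()` returns
#' \deqn{g = -\frac{d_A + d_L}{2} +
#'   \sqrt{\frac{r_A r_L}{c_A c_L} + \frac{(d_A - d_L)^2}{4}},}
#' the exact positive root of the steady-state balance; `gcomm_approx()`
#' drops the \eqn{(d_A - d_L)^2/4} term, which is negligible whenever the
#' release/consumption ratio dominates the death-rate asymmetry.
#'
#' @param d_A,d_L per-hour death rates of the two strains.
#' @param r_A,r_L release rates (fmole/cell/h).
#' @param c_A,c_L consumption per birth (fmole/cell), > 0.
#' @return growth rate in per h.
#' @examples
#' gcomm_exact(0.015, 0.0024, 0.27, 0.78, 3.1, 5.4)
#' @export
gcomm_exact <- function(d_A, d_L, r_A, r_L, c_A, c_L) {
  check_gcomm_args(d_A, d_L, r_A, r_L, c_A, c_L)
  -(d_A + d_L) / 2 + sqrt(r_A * r_L / (c_A * c_L) + (d_A - d_L)^2 / 4)
}

#' @rdname gcomm_exact
#' @export
gcomm_approx <- function(d_A, d_L, r_A, r_L, c_A, c_L) {
  check_gcomm_args(d_A, d_L, r_A, r_L, c_A, c_L)
  -(d_A + d_L) / 2 + sqrt(r_A * r_L / (c_A * c_L))
}

#' Community growth rate with a growth-rate-dependent lysine release
#'
#' Substitutes a linear release law `r_L(g) = intercept + slope * g` into the
#' approximate steady-state balance. Expanding
#' \deqn{\left(g + \frac{d_A + d_L}{2}\right)^2 =
#'   \frac{r_A}{c_A c_L}(\mathrm{intercept} + \mathrm{slope}\, g)}
#' gives a monic quadratic `g^2 + B g + C = 0`; the larger (physically
#' sustained) root is returned.
#'
#' @inheritParams gcomm_exact
#' @param law a [release_law_linear()]; the slope is expected to be negative
#'   over the relevant range (release declines as the releaser grows faster).
#' @return a list with `g_comm` (per h), the monic quadratic coefficients
#'   `linear_coef` (B) and `constant_coef` (C), and the implied `r_L` at the
#'   returned growth rate.
#' @examples
#' gcomm_variable_release(0.015, 0.0024, 0.27, 3.1, 5.4,
#'                        cosmo_linear_release_law())
#' @export
gcomm_variable_release <- function(d_A, d_L, r_A, c_A, c_L, law) {
  if (!inherits(law, "release_law") || law$type != "linear")
    stop("'law' must be a linear release_law")
  check_gcomm_args(d_A, d_L, r_A, max(law$intercept, 0), c_A, c_L)
  m <- (d_A + d_L) / 2
  k <- r_A / (c_A * c_L)
  B <- 2 * m - k * law$slope
  C <- m^2 - k * law$intercept
  disc <- B^2 - 4 * C
  if (disc < 0) stop("no real root: community cannot sustain growth")
  g <- (-B + sqrt(disc)) / 2
  if (g <= 0) stop("no positive root: community cannot sustain growth")
  list(g_comm = g, linear_coef = B, constant_coef = C,
       r_L = release_rate(law, g = g))
}

#' Doubling time of an exponential rate
#'
#' @param g growth rate (per h), > 0.
#' @return `ln(2)/g` in hours.
#' @export
doubling_time <- function(g) {
  if (any(g <= 0)) stop("growth rate must be > 0")
  log(2) / g
}

#' Analytic partial derivatives of the approximate growth rate
#'
#' Partials of [gcomm_approx()] with respect to its six parameters, used by
#' the variance-formula error propagation:
#' `dg/dd = -1/2` for both death rates, `dg/dr = S/(2r)` and
#' `dg/dc = -S/(2c)` where `S = sqrt(r_A r_L / (c_A c_L))`.
#'
#' @inheritParams gcomm_exact
#' @return named numeric vector of the six partials.
#' @export
gcomm_partials <- function(d_A, d_L, r_A, r_L, c_A, c_L) {
  check_gcomm_args(d_A, d_L, r_A, r_L, c_A, c_L)
  S <- sqrt(r_A * r_L / (c_A * c_L))
  c(d_A = -0.5, d_L = -0.5,
    r_A = S / (2 * r_A), r_L = S / (2 * r_L),
    c_A = -S / (2 * c_A), c_L = -S / (2 * c_L))
}

#' Variance-formula error propagation for the predicted growth rate
#'
#' Propagates per-parameter SEMs through [gcomm_approx()]:
#' \deqn{s_g^2 = \sum_i \left(\frac{\partial g}{\partial x_i} s_i\right)^2.}
#' By default the six parameters and SEMs come from the packaged registry,
#' with the lysine release rate fixed at the 7-h-doubling chemostat value
#' (0.78, SEM 0.04) — the environment closest to the community's own doubling
#' time.
#'
#' @param values,sems named numeric vectors with entries `d_A`, `d_L`, `r_A`,
#'   `r_L`, `c_A`, `c_L`; defaults from [default_gcomm_inputs()]. All SEMs
#'   must be >= 0.
#' @return an object of class `growth_prediction`: a list with `g_comm`,
#'   `doubling_time_h`, `sem`, `ci95_half` (= 2 SEM) and `terms`, the named
#'   per-parameter squared contributions (which sum to `sem^2`).
#' @examples
#' propagate_error()
#' @export
propagate_error <- function(values = default_gcomm_inputs()$values,
                            sems = default_gcomm_inputs()$sems) {
  need <- c("d_A", "d_L", "r_A", "r_L", "c_A", "c_L")
  if (!all(need %in% names(values)) || !all(need %in% names(sems)))
    stop("'values' and 'sems' must name all of: ",
         paste(need, collapse = ", "))
  values <- values[need]
  sems <- sems[need]
  if (any(sems < 0)) stop("SEMs must be >= 0")
  g <- do.call(gcomm_approx, as.list(values))
  partials <- do.call(gcomm_partials, as.list(values))
  terms <- (partials * sems)^2
  sem <- sqrt(sum(terms))
  structure(list(g_comm = g, doubling_time_h = doubling_time(g),
                 sem = sem, ci95_half = 2 * sem, terms = terms),
            class = "growth_prediction")
}

#' @export
print.growth_prediction <- function(x, ...) {
  cat(sprintf("Predicted community growth rate: %.4f /h (doubling %.2f h)\n",
              x$g_comm, x$doubling_time_h))
  cat(sprintf("  propagated SEM %.4f; 95%% CI half-width %.4f\n",
              x$sem, x$ci95_half))
  invisible(x)
}
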