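# Domain types and the packaged strain-phenotype registry.

#' Moser birth-model parameters
#'
#' The Moser model generalises Monod kinetics with a cooperativity exponent:
#' `b(s) = b_max * s^n / (s^n + K^n)`, where `s` is the concentration of the
#' limiting metabolite.
#'
#' @param b_max maximal birth rate (per h), > 0.
#' @param K concentration (uM) at which half-maximal birth rate is reached,
#'   > 0.
#' @param n dimensionless cooperativity (akin to a Hill coefficient), > 0.
#' @return an object of class `moser_params`.
#' @examples
#' moser_params(b_max = 0.51, K = 2.1, n = 3.2)
#' @export
moser_params <- function(b_max, K, n) {
  for (nm in c("b_max", "K", "n")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  structure(list(b_max = b_max, K = K, n = n), class = "moser_params")
}

#' Release-rate laws
#'
#' A release rate can be a fixed per-cell rate, a linear function of the
#' releasing strain's net growth rate `g` (fmole/cell/h), or a piecewise-linear
#' function of the local concentration `H` (uM) of the metabolite the releaser
#' itself consumes. Outside the knot range a piecewise law is clamped to its
#' end values; a linear law is clamped below at zero.
#'
#' @param intercept,slope coefficients of the linear law `r(g) = intercept +
#'   slope * g`.
#' @param H,r knot positions (uM, strictly increasing) and release rates
#'   (fmole/cell/h, >= 0) of the piecewise-linear law.
#' @return an object of class `release_law` with `type` `"linear"` or
#'   `"table"`.
#' @export
release_law_linear <- function(intercept, slope) {
  stopifnot(is.numeric(intercept), is.numeric(slope),
            length(intercept) == 1L, length(slope) == 1L)
  structure(list(type = "linear", intercept = intercept, slope = slope),
            class = "release_law")
}

#' @rdname release_law_linear
#' @export
release_law_table <- function(H, r) {
  if (length(H) < 2L) stop("piecewise release law needs >= 2 knots")
  if (length(H) != length(r)) stop("'H' and 'r' must have equal length")
  if (any(diff(H) <= 0)) stop("knot positions 'H' must be strictly increasing")
  if (any(r < 0)) stop("release rates must be >= 0")
  structure(list(type = "table", H = as.numeric(H), r = as.numeric(r)),
            class = "release_law")
}

#' Evaluate a release-rate law
#'
#' @param law a `release_law` or a single fixed numeric rate.
#' @param g net growth rate (per h) of the releasing strain; used by linear
#'   laws.
#' @param H local concentration (uM) of the metabolite limiting the releaser;
#'   used by piecewise laws.
#' @return release rate(s) in fmole/cell/h, clamped at >= 0.
#' @export
release_rate <- function(law, g = NULL, H = NULL) {
  if (is.numeric(law)) return(law)
  stopifnot(inherits(law, "release_law"))
  if (law$type == "linear") {
    if (is.null(g)) stop("linear release law requires the net growth rate 'g'")
    pmax(0, law$intercept + law$slope * g)
  } else {
    if (is.null(H)) stop("piecewise release law requires the concentration 'H'")
    interpolate_release_rate(H, law)
  }
}

#' Interpolate a piecewise-linear release law
#'
#' Linear interpolation between knots, clamped to the end values outside the
#' knot range.
#'
#' @param H concentration(s) in uM.
#' @param law a piecewise (`"table"`) `release_law`.
#' @return release rate(s) in fmole/cell/h.
#' @examples
#' law <- release_law_table(H = c(0, 0.58, 0.65), r = c(0.52, 0.83, 0.78))
#' interpolate_release_rate(0.58, law)
#' @export
interpolate_release_rate <- function(H, law) {
  if (!inherits(law, "release_law") || law$type != "table")
    stop("'law' must be a piecewise ('table') release_law")
  pmax(0, stats::approx(law$H, law$r, xout = H, rule = 2)$y)
}

#' Standard error of the mean from a 95% confidence interval
#'
#' Registry bounds are mean plus/minus 2 SEM, so the SEM is the interval
#' half-width divided by 2, i.e. `(upper - lower) / 4`.
#'
#' @param lower,upper interval bounds, `upper >= lower`. Vectorised.
#' @return SEM(s).
#' @examples
#' sem_from_bounds(0.25, 0.29) # 0.01
#' @export
sem_from_bounds <- function(lower, upper) {
  if (any(upper < lower)) stop("upper bound is below lower bound")
  (upper - lower) / 4
}

#' Strain phenotype
#'
#' Bundles one strain's birth model, death rate, consumption per birth and
#' release rate, with optional 95% confidence bounds (mean +/- 2 SEM) per
#' parameter.
#'
#' @param birth a [moser_params()] object.
#' @param death per-hour death rate, >= 0.
#' @param consumption fmole of metabolite consumed per cell birth, > 0.
#' @param release fixed release rate (fmole/cell/h, >= 0) or a
#'   [release_law_linear()] / [release_law_table()] object.
#' @param bounds named list of `c(lower, upper)` vectors for any of
#'   `b_max`, `K`, `n`, `death`, `consumption`, `release`.
#' @param strain optional strain label.
#' @return an object of class `strain_phenotype`.
#' @export
strain_phenotype <- function(birth, death, consumption, release,
                             bounds = list(), strain = NULL) {
  stopifnot(inherits(birth, "moser_params"))
  if (!is.numeric(death) || death < 0) stop("death rate must be >= 0")
  if (!is.numeric(consumption) || consumption <= 0)
    stop("consumption per birth must be > 0")
  if (is.numeric(release)) {
    if (release < 0) stop("release rate must be >= 0")
  } else if (!inherits(release, "release_law")) {
    stop("'release' must be numeric or a release_law")
  }
  known <- c("b_max", "K", "n", "death", "consumption", "release")
  vals <- c(b_max = birth$b_max, K = birth$K, n = birth$n, death = death,
            consumption = consumption,
            release = if (is.numeric(release)) release else NA_real_)
  for (nm in names(bounds)) {
    if (!nm %in% known) stop(sprintf("unknown bounded field '%s'", nm))
    b <- bounds[[nm]]
    if (length(b) != 2L || b[2] < b[1])
      stop(sprintf("bounds for '%s' must be c(lower, upper) with upper >= lower", nm))
    v <- vals[[nm]]
    if (!is.na(v) && (v < b[1] || v > b[2]))
      stop(sprintf("value of '%s' lies outside its bounds", nm))
  }
  structure(list(birth = birth, death = death, consumption = consumption,
                 release = release, bounds = bounds, strain = strain),
            class = "strain_phenotype")
}

#' @rdname strain_phenotype
#' @param phen a `strain_phenotype`.
#' @param param name of a bounded field.
#' @return `phenotype_sem()`: the SEM derived from the stored bounds.
#' @export
phenotype_sem <- function(phen, param) {
  b <- phen$bounds[[param]]
  if (is.null(b)) stop(sprintf("no bounds stored for '%s'", param))
  sem_from_bounds(b[1], b[2])
}

## ---- parameter registry -------------------------------------------------

registry_required_cols <- c("strain", "parameter", "value", "lower", "upper",
                            "unit")

registry_expected_unit <- function(parameter) {
  base <- sub("\\(.*\\)$", "", parameter)
  switch(base,
         b_max = "per_h", K = "uM", n = "dimensionless", d = "per_h",
         c = "fmole_per_cell", r = "fmole_per_cell_per_h",
         r_L = "fmole_per_cell_per_h",
         NA_character_)
}

#' Load a strain-phenotype parameter registry
#'
#' The registry is a flat CSV with columns `strain, parameter, value, lower,
#' upper, unit`; `lower`/`upper` are 95% confidence bounds (mean +/- 2 SEM).
#' Growth-rate-dependent lysine release rates are stored as rows named
#' `r_L(H=<uM>)`.
#'
#' @param path path to the registry CSV. Lines starting with `#` are ignored.
#' @return a data frame of class `param_registry`.
#' @seealso [cosmo_registry()] for the packaged registry,
#'   [write_parameter_table()] for the inverse operation.
#' @export
load_parameter_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("registry file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(strain = "character"))
  missing <- setdiff(registry_required_cols, names(df))
  if (length(missing))
    stop(sprintf("registry is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  for (col in c("value", "lower", "upper")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(is.na(df[[col]])))
      stop(sprintf("non-numeric entries in column '%s'", col))
  }
  bad <- df$lower > df$value | df$value > df$upper
  if (any(bad))
    stop(sprintf("bound ordering violated for %s/%s",
                 df$strain[bad][1], df$parameter[bad][1]))
  exp_unit <- vapply(df$parameter, registry_expected_unit, character(1))
  if (any(is.na(exp_unit)))
    stop(sprintf("unknown parameter '%s'", df$parameter[is.na(exp_unit)][1]))
  wrong <- df$unit != exp_unit
  if (any(wrong))
    stop(sprintf("unexpected unit '%s' for parameter '%s' (expected '%s')",
                 df$unit[wrong][1], df$parameter[wrong][1],
                 exp_unit[wrong][1]))
  class(df) <- c("param_registry", "data.frame")
  df
}

#' Write a parameter registry to CSV
#'
#' Numeric fields are written at full double precision so that
#' [load_parameter_table()] round-trips every value bit-exactly.
#'
#' @param registry a `param_registry` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(registry, path) {
  out <- registry
  for (col in c("value", "lower", "upper"))
    out[[col]] <- sprintf("%.17g", registry[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# strain phenotype registry; bounds are mean +/- 2 SEM", con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a parameter registry as JSON
#'
#' @inheritParams write_parameter_table
#' @export
export_parameter_json <- function(registry, path) {
  jsonlite::write_json(as.data.frame(registry), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' The packaged strain-phenotype registry
#'
#' Chemostat- and batch-measured phenotypes of the lysine auxotroph
#' (strain 1335, L-A+) and the purine auxotroph (strain 1340, A-L+):
#' Moser birth parameters, chemostat death rates, consumption per birth, the
#' hypoxanthine release rate of L-A+, and the lysine release rate of A-L+ as a
#' function of the hypoxanthine concentration `H` it experienced (rows
#' `r_L(H=...)`, spanning starvation to a 4-h doubling time).
#'
#' @return a `param_registry` data frame.
#' @export
cosmo_registry <- function() {
  load_parameter_table(system.file("extdata", "strain_phenotypes.csv",
                                   package = "cosmor", mustWork = TRUE))
}

#' Look up a registry value, bounds or SEM
#'
#' @param registry a `param_registry`.
#' @param strain strain id (e.g. `"1335"`).
#' @param parameter parameter name (e.g. `"c"`, `"r_L(H=0.65)"`).
#' @return `registry_value()`: the point value; `registry_sem()`: the SEM
#'   derived from the bounds.
#' @export
registry_value <- function(registry, strain, parameter) {
  row <- registry$strain == as.character(strain) &
    registry$parameter == parameter
  if (sum(row) != 1L)
    stop(sprintf("registry has %d rows for %s/%s", sum(row), strain, parameter))
  registry$value[row]
}

#' @rdname registry_value
#' @export
registry_sem <- function(registry, strain, parameter) {
  row <- registry$strain == as.character(strain) &
    registry$parameter == parameter
  if (sum(row) != 1L)
    stop(sprintf("registry has %d rows for %s/%s", sum(row), strain, parameter))
  sem_from_bounds(registry$lower[row], registry$upper[row])
}

registry_bounds <- function(registry, strain, parameter) {
  row <- registry$strain == as.character(strain) &
    registry$parameter == parameter
  c(registry$lower[row], registry$upper[row])
}

#' Strain phenotypes from a registry
#'
#' Builds `strain_phenotype` objects for both community members. The lysine
#' release of the purine auxotroph is returned as a piecewise-linear
#' [release_law_table()] over the `r_L(H=...)` rows.
#'
#' @param registry a `param_registry`; defaults to the packaged registry.
#' @return a list with elements `LA` (strain 1335, the lysine auxotroph that
#'   releases hypoxanthine) and `AL` (strain 1340, the purine auxotroph that
#'   releases lysine).
#' @export
registry_phenotypes <- function(registry = cosmo_registry()) {
  phen <- function(strain, release) {
    strain_phenotype(
      birth = moser_params(registry_value(registry, strain, "b_max"),
                           registry_value(registry, strain, "K"),
                           registry_value(registry, strain, "n")),
      death = registry_value(registry, strain, "d"),
      consumption = registry_value(registry, strain, "c"),
      release = release,
      bounds = list(
        b_max = registry_bounds(registry, strain, "b_max"),
        K = registry_bounds(registry, strain, "K"),
        n = registry_bounds(registry, strain, "n"),
        death = registry_bounds(registry, strain, "d"),
        consumption = registry_bounds(registry, strain, "c")
      ),
      strain = strain
    )
  }
  la <- phen("1335", registry_value(registry, "1335", "r"))
  la$bounds$release <- registry_bounds(registry, "1335", "r")
  list(LA = la, AL = phen("1340", cosmo_table_release_law(registry)))
}

#' Lysine release laws of the purine auxotroph
#'
#' `cosmo_table_release_law()` builds the piecewise-linear law r_L(H) from the
#' registry's `r_L(H=...)` rows (used in spatial simulations, where the local
#' hypoxanthine concentration is known). `cosmo_linear_release_law()` returns
#' the linear regression of chemostat lysine release rates on the net growth
#' rate over the community-relevant range of doubling times (5.5-8 h),
#' `r_L(g) = 1.853 - 11.388 g` (used in the closed-form steady-state
#' prediction, where growth rate is the natural variable).
#'
#' @param registry a `param_registry`.
#' @return a `release_law`.
#' @export
cosmo_table_release_law <- function(registry = cosmo_registry()) {
  rows <- grepl("^r_L\\(H=", registry$parameter) & registry$strain == "1340"
  if (!any(rows)) stop("registry has no r_L(H=...) rows for strain 1340")
  H <- as.numeric(sub("^r_L\\(H=([0-9.]+)\\)$", "\\1",
                      registry$parameter[rows]))
  ord <- order(H)
  release_law_table(H[ord], registry$value[rows][ord])
}

#' @rdname cosmo_table_release_law
#' @export
cosmo_linear_release_law <- function() {
  release_law_linear(intercept = 1.853, slope = -11.388)
}

#' Default inputs for the steady-state growth-rate prediction
#'
#' Assembles the six scalar parameters of the closed-form community growth
#' rate and their SEMs from a registry. The lysine release rate is taken from
#' the chemostat row whose doubling time most closely matches the community's
#' (7 h, i.e. the `r_L(H=0.65)` row, 0.78 fmole/cell/h).
#'
#' @param registry a `param_registry`.
#' @param r_L_row registry row name used for the fixed lysine release rate.
#' @return a list with numeric vectors `values` and `sems`, each with names
#'   `d_A`, `d_L`, `r_A`, `r_L`, `c_A`, `c_L`.
#' @export
default_gcomm_inputs <- function(registry = cosmo_registry(),
                                 r_L_row = "r_L(H=0.65)") {
  values <- c(d_A = registry_value(registry, "1340", "d"),
              d_L = registry_value(registry, "1335", "d"),
              r_A = registry_value(registry, "1335", "r"),
              r_L = registry_value(registry, "1340", r_L_row),
              c_A = registry_value(registry, "1340", "c"),
              c_L = registry_value(registry, "1335", "c"))
  sems <- c(d_A = registry_sem(registry, "1340", "d"),
            d_L = registry_sem(registry, "1335", "d"),
            r_A = registry_sem(registry, "1335", "r"),
            r_L = registry_sem(registry, "1340", r_L_row),
            c_A = registry_sem(registry, "1340", "c"),
            c_L = registry_sem(registry, "1335", "c"))
  list(values = values, sems = sems)
}
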