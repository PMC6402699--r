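# CSV/JSON readers and writers and the configuration-driven pipeline runner
# that ties the modules together.

trajectory_cols <- c("time_h", "NL_per_ml", "NA_per_ml", "L_uM", "A_uM")
chemostat_cols <- c("time_h", "live_per_ml", "dead_per_ml", "limiting_uM",
                    "released_uM")

#' Write / read a time-series CSV
#'
#' Numeric values are written at full double precision (`%.17g`) under a
#' `#`-prefixed metadata header (package version, optional seed and extra
#' fields — never a timestamp, so identical inputs give byte-identical
#' files); `read_series_csv()` round-trips every number bit-exactly and
#' returns the metadata as an attribute.
#'
#' @param df data frame (e.g. a `cosmo_trajectory` or `chemostat_series`).
#' @param path output path.
#' @param seed optional integer recorded in the header.
#' @param meta named list of extra header fields.
#' @return `path` (write) or the data frame with attribute `meta` (read).
#' @export
write_series_csv <- function(df, path, seed = NULL, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cosmor %s", as.character(utils::packageVersion("cosmor"))),
             con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, as.character(meta[[nm]])), con)
  out <- as.data.frame(df)
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        stringsAsFactors = FALSE)
  attr(df, "meta") <- sub("^# ?", "", hdr)
  df
}

#' Steady-state growth-rate report
#'
#' Runs the closed-form prediction with either the variable (linear) lysine
#' release law or a fixed release rate, plus the variance-formula error
#' propagation, and assembles a JSON-ready report.
#'
#' @param registry a `param_registry`.
#' @param release `"linear"` for the growth-rate-dependent law, or a single
#'   fixed rate (fmole/cell/h).
#' @param propagate include error propagation (always uses the fixed
#'   7-h-chemostat release rate, the environment matching the community's
#'   doubling time).
#' @return a list with `g_comm`, `doubling_time_h`, quadratic coefficients
#'   (variable-release case), and `sem`/`ci95_half`/`terms` when propagated.
#' @export
gcomm_report <- function(registry = cosmo_registry(), release = "linear",
                         propagate = TRUE) {
  inputs <- default_gcomm_inputs(registry)
  v <- inputs$values
  report <- if (identical(release, "linear")) {
    q <- gcomm_variable_release(v[["d_A"]], v[["d_L"]], v[["r_A"]],
                                v[["c_A"]], v[["c_L"]],
                                cosmo_linear_release_law())
    list(release_law = "linear", g_comm = q$g_comm,
         doubling_time_h = doubling_time(q$g_comm),
         quadratic_linear_coef = q$linear_coef,
         quadratic_constant_coef = q$constant_coef,
         r_L_at_g = q$r_L)
  } else {
    v[["r_L"]] <- release
    g <- do.call(gcomm_approx, as.list(v))
    list(release_law = "fixed", r_L = release, g_comm = g,
         doubling_time_h = doubling_time(g))
  }
  if (propagate) {
    pe <- propagate_error(inputs$values, inputs$sems)
    report$sem <- pe$sem
    report$ci95_half <- pe$ci95_half
    report$error_terms <- as.list(pe$terms)
  }
  report
}

#' @rdname gcomm_report
#' @param report a report list.
#' @param path output JSON path.
#' @export
write_gcomm_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_error <- function(msg) {
  stop(structure(class = c("cosmor_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Run a configured pipeline stage
#'
#' Executes one analysis task described by a declarative configuration (a
#' named list or a YAML file with the same structure). Supported tasks:
#'
#' * `predict_gcomm`: closed-form growth-rate prediction; writes a JSON
#'   report (`out`).
#' * `simulate_wellmixed`: community trajectory CSV (`t_end`, `out`).
#' * `simulate_chemostat`: chemostat series CSV (`strain`, `doubling` or
#'   `dil`, `supply_conc`, `t_end`, `out`).
#' * `synth_chemostat`: noisy synthetic chemostat series CSV (as above plus
#'   `seed`).
#' * `estimate_release` / `estimate_death`: regression estimates from a
#'   series CSV (`series`, `dil`); result appended to the returned list.
#'
#' Every file written carries a metadata header with the package version and
#' the seed; invalid configurations raise a `cosmor_config_error` naming the
#' offending field.
#'
#' @param config named list, or path to a YAML file.
#' @return a list with the task name, any computed estimates, and the paths
#'   of written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      config_error(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  task <- config$task %||% config_error("missing field 'task'")
  seed <- as.integer(config$seed %||% 1L)
  registry <- if (!is.null(config$params)) {
    if (!file.exists(config$params))
      config_error(sprintf("params file not found: %s", config$params))
    load_parameter_table(config$params)
  } else cosmo_registry()
  phen <- registry_phenotypes(registry)
  artifacts <- character(0)
  result <- NULL

  if (task == "predict_gcomm") {
    report <- gcomm_report(registry,
                           release = config$release %||% "linear",
                           propagate = config$propagate %||% TRUE)
    if (!is.null(config$out)) {
      write_gcomm_report(report, config$out)
      artifacts <- config$out
    }
    result <- report
  } else if (task == "simulate_wellmixed") {
    t_end <- config$t_end %||% config_error("missing field 't_end'")
    traj <- simulate_wellmixed(phen, t_end = t_end)
    if (!is.null(config$out)) {
      write_series_csv(traj, config$out, seed = seed, meta = list(task = task))
      artifacts <- config$out
    }
    result <- traj
  } else if (task %in% c("simulate_chemostat", "synth_chemostat")) {
    strain_id <- as.character(config$strain %||% "1335")
    strain <- if (strain_id == "1335") phen$LA else phen$AL
    cfg <- chemostat_config(supply_conc = config$supply_conc %||% 20,
                            dil = config$dil, doubling = config$doubling)
    t_end <- config$t_end %||% config_error("missing field 't_end'")
    ser <- if (task == "simulate_chemostat") {
      simulate_chemostat(strain, cfg, t_end = t_end)
    } else {
      generate_chemostat_series(strain, cfg,
                                times = seq(0, t_end,
                                            by = config$sample_every %||% 3),
                                seed = seed)
    }
    if (!is.null(config$out)) {
      write_series_csv(ser, config$out, seed = seed, meta = list(task = task))
      artifacts <- config$out
    }
    result <- ser
  } else if (task %in% c("estimate_release", "estimate_death")) {
    path <- config$series %||% config_error("missing field 'series'")
    ser <- read_series_csv(path)
    dil <- config$dil %||% config_error("missing field 'dil'")
    result <- if (task == "estimate_release")
      estimate_release_regression(ser, dil)
    else estimate_death_regression(ser, dil)
  } else {
    config_error(sprintf("unknown task '%s'", task))
  }
  invisible(list(task = task, result = result, artifacts = artifacts,
                 seed = seed))
}
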