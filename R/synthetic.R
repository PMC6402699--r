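# Synthetic-data generators: forward models plus multiplicative measurement
# noise emulating flow-cytometry density counts (CV ~5-10%) and metabolite
# bioassays. All generators are deterministic under a fixed seed and embed
# the generating truth as attributes.

#' Measurement-noise model
#'
#' Multiplicative lognormal noise, independent across time points and
#' channels: an observation is `latent * exp(sigma Z - sigma^2/2)` with
#' `sigma = sqrt(log(1 + CV^2))`, which preserves the latent mean and is
#' positivity-preserving.
#'
#' @param cv_density coefficient of variation for cell-density measurements
#'   (default 0.075, mid-range of the 5-10% flow-cytometry triplicate CV).
#' @param cv_metabolite coefficient of variation for metabolite assays.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(cv_density = 0.075, cv_metabolite = 0.10) {
  if (cv_density < 0 || cv_metabolite < 0) stop("CVs must be >= 0")
  structure(list(cv_density = cv_density, cv_metabolite = cv_metabolite),
            class = "noise_model")
}

apply_noise <- function(x, cv) {
  if (cv == 0) return(x)
  s <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), 0, s) - s^2 / 2)
}

#' Synthetic chemostat time course
#'
#' Noiseless latent dynamics from [simulate_chemostat()], observed with
#' multiplicative noise (density channels at `cv_density`, metabolite
#' channels at `cv_metabolite`).
#'
#' @param strain a [strain_phenotype()] — the generating truth.
#' @param cfg a [chemostat_config()].
#' @param times sampling times (h); default the chemostat assay cadence,
#'   every 3 h to 96 h.
#' @param noise a [noise_model()].
#' @param seed integer seed; identical seeds give identical output.
#' @return a `chemostat_series` with attributes `truth` (the strain), `seed`
#'   and `latent` (the noiseless series).
#' @export
generate_chemostat_series <- function(strain, cfg,
                                      times = seq(0, 96, by = 3),
                                      noise = noise_model(), seed = 1L) {
  latent <- simulate_chemostat(strain, cfg, t_end = max(times), times = times)
  set.seed(seed)
  obs <- latent
  obs$live_per_ml <- apply_noise(latent$live_per_ml, noise$cv_density)
  obs$dead_per_ml <- apply_noise(latent$dead_per_ml, noise$cv_density)
  obs$limiting_uM <- apply_noise(latent$limiting_uM, noise$cv_metabolite)
  obs$released_uM <- apply_noise(latent$released_uM, noise$cv_metabolite)
  attr(obs, "truth") <- strain
  attr(obs, "seed") <- seed
  attr(obs, "latent") <- latent
  obs
}

#' Synthetic starvation-release time course
#'
#' A starving population (no births) dying at a possibly two-phase rate,
#' releasing metabolite either from live cells at a constant per-cell rate or
#' upon death at a fixed amount per death. The default two-phase death rate
#' (slow early, fast late) mirrors observed starvation kinetics and is what
#' makes the two release modes structurally distinguishable: with a constant
#' death rate and no dilution, the dead density is exactly proportional to
#' the integrated live density and the modes are confounded.
#'
#' @param N0 initial live density (cells/mL).
#' @param release_mode `"live"` or `"dead"`.
#' @param r live release rate (fmole/cell/h); used in live mode.
#' @param r_dead amount released per death (fmole/cell); used in dead mode.
#' @param death death rate (per h): a single value for a constant rate, or
#'   `c(early, late)` with the switch at `t_switch`.
#' @param t_switch time (h) of the early-to-late death-rate switch.
#' @param dead0_frac initial dead pool as a fraction of `N0` (washed-in dead
#'   cells; they contribute no released metabolite).
#' @param times sampling times (h); default every 6 h to 24 h (the
#'   lysine-auxotroph assay cadence; use e.g. `seq(0, 90, 10)` for the
#'   partner's longer, sparser assay).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return data frame with `time_h`, `live_per_ml`, `dead_per_ml`,
#'   `metabolite_uM`; attributes `truth`, `seed`, `latent`.
#' @export
generate_starvation_series <- function(N0 = 3e6,
                                       release_mode = c("live", "dead"),
                                       r = 0.52, r_dead = 50,
                                       death = c(0.003, 0.02), t_switch = 12,
                                       dead0_frac = 0.05,
                                       times = seq(0, 24, by = 6),
                                       noise = noise_model(), seed = 1L) {
  release_mode <- match.arg(release_mode)
  if (length(death) == 1L) death <- c(death, death)
  d1 <- death[1L]
  d2 <- death[2L]
  dead0 <- dead0_frac * N0

  live_at <- function(t) ifelse(t <= t_switch, N0 * exp(-d1 * t),
                                N0 * exp(-d1 * t_switch - d2 * (t - t_switch)))
  int_exp <- function(d, n0, t) if (d == 0) n0 * t else n0 * (1 - exp(-d * t)) / d
  int_live <- function(t) {
    ifelse(t <= t_switch, int_exp(d1, N0, pmin(t, t_switch)),
           int_exp(d1, N0, t_switch) +
             int_exp(d2, live_at(t_switch), pmax(t - t_switch, 0)))
  }
  live <- live_at(times)
  deaths_cum <- N0 - live            # deaths since t = 0
  dead <- dead0 + deaths_cum
  M <- if (release_mode == "live") r * int_live(times) * FMOLE_PER_ML_TO_UM
       else r_dead * deaths_cum * FMOLE_PER_ML_TO_UM

  latent <- data.frame(time_h = times, live_per_ml = live, dead_per_ml = dead,
                       metabolite_uM = M)
  set.seed(seed)
  obs <- latent
  obs$live_per_ml <- apply_noise(live, noise$cv_density)
  obs$dead_per_ml <- apply_noise(dead, noise$cv_density)
  obs$metabolite_uM <- apply_noise(M, noise$cv_metabolite)
  attr(obs, "truth") <- list(release_mode = release_mode, r = r,
                             r_dead = r_dead, death = death,
                             t_switch = t_switch, N0 = N0, dead0 = dead0)
  attr(obs, "seed") <- seed
  attr(obs, "latent") <- latent
  obs
}

#' Synthetic well-mixed community trajectory with dilution events
#'
#' Wraps [simulate_wellmixed()]: whenever the raw (observed) total live
#' density exceeds `dilution_threshold`, the culture is diluted
#' `dilution_factor`-fold with fresh medium. Dilution is treated as
#' observational bookkeeping: per-capita community dynamics are assumed
#' unperturbed, since the quasi-steady exchanged-metabolite concentrations
#' are set by the strain ratio rather than absolute density (and intracellular
#' stores, not modelled here, buffer brief post-dilution dips). Raw
#' (post-dilution) densities are reported together with the cumulative
#' dilution factor, so [accumulate_densities()] reconstructs the undiluted
#' latent trajectory exactly (up to measurement noise).
#'
#' @inheritParams simulate_wellmixed
#' @param dilution_threshold total live density (cells/mL) that triggers a
#'   dilution; `NULL` disables dilutions.
#' @param dilution_factor fold-dilution applied at each event.
#' @param dt output sampling interval (h).
#' @param noise a [noise_model()] applied to the density and metabolite
#'   channels.
#' @param seed integer seed.
#' @return a `cosmo_trajectory` with an extra `dilution_factor` column
#'   (cumulative) and attributes `events`, `truth`, `seed`, `latent`.
#' @export
generate_cosmo_trajectory <- function(phenotypes,
                                      init = c(NL_per_ml = 5e4,
                                               NA_per_ml = 5e4,
                                               L_uM = 0, A_uM = 0),
                                      t_end = 72, dt = 1,
                                      dilution_threshold = NULL,
                                      dilution_factor = 10,
                                      noise = noise_model(), seed = 1L) {
  times <- seq(0, t_end, by = dt)
  undiluted <- simulate_wellmixed(phenotypes, init = init, t_end = t_end,
                                  times = times)
  density_cols <- c("NL_per_ml", "NA_per_ml", "deadL_per_ml", "deadA_per_ml")
  events <- data.frame(time = numeric(0), factor = numeric(0))
  cumfac <- rep(1, length(times))
  fac <- 1
  for (i in seq_along(times)) {
    tot_raw <- (undiluted$NL_per_ml[i] + undiluted$NA_per_ml[i]) / fac
    if (!is.null(dilution_threshold) && tot_raw > dilution_threshold &&
        times[i] > 0) {
      fac <- fac * dilution_factor
      events <- rbind(events, data.frame(time = times[i],
                                         factor = dilution_factor))
    }
    cumfac[i] <- fac
  }
  latent <- undiluted
  for (col in density_cols) latent[[col]] <- undiluted[[col]] / cumfac
  latent$dilution_factor <- cumfac
  set.seed(seed)
  obs <- latent
  for (col in c("NL_per_ml", "NA_per_ml", "deadL_per_ml", "deadA_per_ml"))
    obs[[col]] <- apply_noise(latent[[col]], noise$cv_density)
  for (col in c("L_uM", "A_uM"))
    obs[[col]] <- apply_noise(latent[[col]], noise$cv_metabolite)
  class(obs) <- c("cosmo_trajectory", "data.frame")
  attr(obs, "events") <- events
  attr(obs, "truth") <- phenotypes
  attr(obs, "seed") <- seed
  attr(obs, "latent") <- latent
  obs
}
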