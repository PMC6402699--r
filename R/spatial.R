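# Reduced-scale spatial community simulator: metabolites diffuse through an
# agarose column; biomass sits in a single surface layer, grows on the local
# metabolite, consumes per birth and releases per cell-hour. Continuum
# biomass densities replace individual cells — release and consumption scale
# linearly with biomass, so the continuum limit is equivalent for
# growth-rate purposes.

#' Spatial simulation configuration
#'
#' The default desk-scale domain (160 x 160 um laterally at 20-um spacing,
#' 5-mm agarose depth at 0.5-mm vertical spacing) is deliberately reduced
#' from plate scale; the geometry, diffusion coefficients and inoculation
#' options mirror the plate setups (uniform filter inoculation at 3,000
#' cells/mm^2, or a central spot covering 1/16 of the domain area).
#'
#' @param domain_um lateral domain edge length (um).
#' @param dx_um lateral grid spacing (um), > 0.
#' @param depth_mm agarose depth (mm).
#' @param dz_um vertical grid spacing (um), > 0.
#' @param D_agar_um2_s metabolite diffusion coefficient in agarose (um^2/s).
#' @param D_community_um2_s diffusion coefficient inside the cell layer
#'   (um^2/s); `NULL` uses the agarose value everywhere (the single-D
#'   option).
#' @param inoculation `"uniform"` or `"spot"` (a central square covering
#'   `spot_fraction` of the domain area).
#' @param spot_fraction fraction of the domain area inoculated in spot mode,
#'   in (0, 1].
#' @param density_per_mm2 initial total cell density over the inoculated
#'   area (cells/mm^2), split 1:1 between the strains.
#' @param init_L_uM,init_A_uM initial uniform metabolite concentrations in
#'   the agarose.
#' @param dt_h time step (h); `NULL` chooses 90% of the explicit-diffusion
#'   stability limit (and at most 0.002 h so the reaction update stays
#'   accurate when diffusion is slow or absent).
#' @param save_every_h interval between recorded population totals (h).
#' @return an object of class `spatial_config`.
#' @export
spatial_config <- function(domain_um = 160, dx_um = 20, depth_mm = 5,
                           dz_um = 500, D_agar_um2_s = 360,
                           D_community_um2_s = NULL,
                           inoculation = c("uniform", "spot"),
                           spot_fraction = 1 / 16,
                           density_per_mm2 = 3000,
                           init_L_uM = 0, init_A_uM = 0,
                           dt_h = NULL, save_every_h = 1) {
  inoculation <- match.arg(inoculation)
  if (dx_um <= 0 || dz_um <= 0) stop("grid spacings must be > 0")
  if (D_agar_um2_s < 0) stop("diffusion coefficient must be >= 0")
  if (spot_fraction <= 0 || spot_fraction > 1)
    stop("'spot_fraction' must be in (0, 1]")
  nx <- max(2L, round(domain_um / dx_um))
  nz <- max(2L, round(depth_mm * 1000 / dz_um))
  structure(list(domain_um = domain_um, dx_um = dx_um, nx = nx, ny = nx,
                 depth_mm = depth_mm, dz_um = dz_um, nz = nz,
                 D_agar_um2_s = D_agar_um2_s,
                 D_community_um2_s = D_community_um2_s,
                 inoculation = inoculation, spot_fraction = spot_fraction,
                 density_per_mm2 = density_per_mm2,
                 init_L_uM = init_L_uM, init_A_uM = init_A_uM,
                 dt_h = dt_h, save_every_h = save_every_h),
            class = "spatial_config")
}

spatial_dt_limit <- function(cfg) {
  D_max_h <- max(cfg$D_agar_um2_s, cfg$D_community_um2_s %||% 0) * 3600
  if (D_max_h == 0) return(Inf)
  1 / (2 * D_max_h * (2 / cfg$dx_um^2 + 1 / cfg$dz_um^2))
}

release_law_params <- function(release) {
  if (is.numeric(release))
    list(law_type = 0L, rL_fixed = release, rL_intercept = 0, rL_slope = 0,
         law_H = c(0, 1), law_r = c(release, release))
  else if (release$type == "linear")
    list(law_type = 1L, rL_fixed = 0, rL_intercept = release$intercept,
         rL_slope = release$slope, law_H = c(0, 1), law_r = c(0, 0))
  else
    list(law_type = 2L, rL_fixed = 0, rL_intercept = 0, rL_slope = 0,
         law_H = release$H, law_r = release$r)
}

#' Simulate spatial community growth on an agarose column
#'
#' Explicit operator-split update: both metabolite fields diffuse (7-point
#' stencil, no-flux boundaries, per-layer diffusion coefficient), then the
#' surface cell layer reacts — Moser birth on the local metabolite, fixed
#' death rate, consumption per birth, release per cell-hour with the lysine
#' release rate evaluated from the A-L+ strain's release law at the local
#' hypoxanthine concentration (piecewise law) or local net growth rate
#' (linear law). A time step above the explicit-diffusion stability limit is
#' rejected before running.
#'
#' @param phenotypes list with `LA` and `AL` [strain_phenotype()] objects.
#' @param cfg a [spatial_config()].
#' @param t_end simulated time (h).
#' @param init_fields optional list with 3-D arrays `L` and `A` (uM) and
#'   lateral matrices `nL`, `nA` (cells per grid element) overriding the
#'   configured initial condition; used to chain runs.
#' @return a list of class `spatial_result`: `totals` (data frame `time_h`,
#'   `total_L_cells`, `total_A_cells`, `total_cells`), final fields `L_uM`
#'   and `A_uM` (3-D arrays, layer 1 = surface), final biomass matrices
#'   `nL`, `nA`, the cumulative release/consumption bookkeeping (fmole), and
#'   the voxel volume.
#' @export
simulate_spatial <- function(phenotypes, cfg, t_end, init_fields = NULL) {
  stopifnot(inherits(cfg, "spatial_config"))
  pL <- phenotypes$LA
  pA <- phenotypes$AL
  limit <- spatial_dt_limit(cfg)
  dt <- cfg$dt_h %||% min(0.9 * limit, 0.002)
  if (dt > limit)
    stop(sprintf(
      "time step %.3g h violates the diffusion stability limit %.3g h",
      dt, limit))
  nx <- cfg$nx; ny <- cfg$ny; nz <- cfg$nz

  if (is.null(init_fields)) {
    L <- array(cfg$init_L_uM, dim = c(nx, ny, nz))
    A <- array(cfg$init_A_uM, dim = c(nx, ny, nz))
    elem_mm2 <- (cfg$dx_um / 1000)^2
    nL <- matrix(0, nx, ny)
    if (cfg$inoculation == "uniform") {
      nL[] <- cfg$density_per_mm2 * elem_mm2 / 2
    } else {
      side <- max(1L, round(nx * sqrt(cfg$spot_fraction)))
      i0 <- floor((nx - side) / 2) + 1L
      sel <- i0:(i0 + side - 1L)
      nL[sel, sel] <- cfg$density_per_mm2 * elem_mm2 / 2 / cfg$spot_fraction
    }
    nA <- nL
  } else {
    L <- init_fields$L; A <- init_fields$A
    nL <- init_fields$nL; nA <- init_fields$nA
  }

  D_layer <- rep(cfg$D_agar_um2_s * 3600, nz)
  if (!is.null(cfg$D_community_um2_s))
    D_layer[1L] <- cfg$D_community_um2_s * 3600

  n_steps <- max(1L, ceiling(t_end / dt))
  record_every <- max(1L, round(cfg$save_every_h / dt))
  params <- c(list(bmaxL = pL$birth$b_max, KL = pL$birth$K, nL = pL$birth$n,
                   bmaxA = pA$birth$b_max, KA = pA$birth$K, nA = pA$birth$n,
                   dL = pL$death, dA = pA$death,
                   cL = pL$consumption, cA = pA$consumption,
                   rA = if (is.numeric(pL$release)) pL$release else
                     stop("the L-A+ release rate must be a fixed value")),
              release_law_params(pA$release))

  res <- .spatial_core(as.numeric(L), as.numeric(A),
                       as.numeric(nL), as.numeric(nA),
                       nx, ny, nz, cfg$dx_um, cfg$dz_um, D_layer,
                       params, dt, n_steps, record_every)
  totals <- data.frame(time_h = res$time_h,
                       total_L_cells = res$total_L_cells,
                       total_A_cells = res$total_A_cells)
  totals$total_cells <- totals$total_L_cells + totals$total_A_cells
  structure(list(
    totals = totals,
    L_uM = array(res$L_field, dim = c(nx, ny, nz)),
    A_uM = array(res$A_field, dim = c(nx, ny, nz)),
    nL = matrix(res$nL, nx, ny), nA = matrix(res$nA, nx, ny),
    bookkeeping = list(release_L = res$cum_release_L_fmole,
                       consumption_L = res$cum_consumption_L_fmole,
                       release_A = res$cum_release_A_fmole,
                       consumption_A = res$cum_consumption_A_fmole),
    voxel_mL = cfg$dx_um^2 * cfg$dz_um * 1e-12,
    dt_h = dt, config = cfg), class = "spatial_result")
}

#' Community-layer versus agarose metabolite means
#'
#' Spatial means of each metabolite in the surface (community) layer and in
#' the agarose below it; at late times the two closely agree, which is why
#' spatially structured and well-mixed communities grow at similar rates.
#'
#' @param result a `spatial_result`.
#' @param community_mask optional logical lateral matrix restricting the
#'   community-layer mean to occupied elements; default: elements with any
#'   biomass.
#' @return data frame with columns `metabolite`, `community_uM`, `agar_uM`.
#' @export
spatial_metabolite_summary <- function(result, community_mask = NULL) {
  mask <- community_mask %||% (result$nL + result$nA > 0)
  agar_idx <- seq(2L, dim(result$L_uM)[3L])
  data.frame(
    metabolite = c("lysine", "hypoxanthine"),
    community_uM = c(mean(result$L_uM[, , 1L][mask]),
                     mean(result$A_uM[, , 1L][mask])),
    agar_uM = c(mean(result$L_uM[, , agar_idx]),
                mean(result$A_uM[, , agar_idx]))
  )
}

#' Total metabolite mass in the domain
#'
#' @param result a `spatial_result`.
#' @return named vector of total lysine and hypoxanthine (fmole).
#' @export
spatial_metabolite_mass <- function(result) {
  to_fmole <- result$voxel_mL / FMOLE_PER_ML_TO_UM
  c(L = sum(result$L_uM) * to_fmole, A = sum(result$A_uM) * to_fmole)
}
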