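---
title: "Modeling the growth of an obligate cross-feeding yeast community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the growth of an obligate cross-feeding yeast community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmor)
```

## The system and the model

CoSMO is an engineered community of two non-mating *S. cerevisiae* strains.
The lysine auxotroph (here "L-A+", strain 1335) cannot make lysine but
overproduces and releases hypoxanthine; the purine auxotroph ("A-L+",
strain 1340) cannot use its own purine pathway but overproduces and releases
lysine. In minimal medium each strain grows only on what its partner
releases, so the pair forms an obligate mutualism.

The well-mixed community model tracks two live populations and two
metabolites:

$$\frac{dN_L}{dt} = (b_L(L) - d_L)\,N_L, \qquad
  \frac{dN_A}{dt} = (b_A(A) - d_A)\,N_A,$$
$$\frac{dL}{dt} = 10^{-6}\,(r_L N_A - c_L\, b_L(L)\, N_L), \qquad
  \frac{dA}{dt} = 10^{-6}\,(r_A N_L - c_A\, b_A(A)\, N_A).$$

Birth rates follow the Moser law $b(s) = b_{max} s^n/(s^n + K^n)$, a Monod
curve with cooperativity $n$. Units are fixed package-wide — hours, cells/mL,
µM, fmole per cell — and the single conversion constant
$1\ \mathrm{fmole/mL} = 10^{-6}\ \mu M$ makes the metabolite equations
dimensionally consistent (e.g. 0.12 fmole/cell released by $10^5$ dead
cells/mL would yield 0.012 µM).

At the community steady state both strains grow at the common rate
$g_{comm}$ and metabolite concentrations are constant, which gives
$r_A r_L = c_A c_L (g + d_L)(g + d_A)$ and the closed forms implemented by
`gcomm_exact()` and `gcomm_approx()`:

$$g_{comm} \approx -\frac{d_A + d_L}{2} + \sqrt{\frac{r_A r_L}{c_A c_L}}.$$

Because the lysine release rate of A-L+ itself declines with growth rate,
the package also solves the self-consistent case
(`gcomm_variable_release()`): substituting the linear law
$r_L(g) = 1.853 - 11.388\,g$ into the balance yields a monic quadratic in
$g_{comm}$ whose positive root is the prediction, $g_{comm} = 0.10$/h
(doubling time about 7 h) with the packaged chemostat phenotypes.

```{r}
v <- default_gcomm_inputs()$values
gcomm_variable_release(v[["d_A"]], v[["d_L"]], v[["r_A"]],
                       v[["c_A"]], v[["c_L"]], cosmo_linear_release_law())
```

## Parameters and their uncertainty

`cosmo_registry()` ships the measured strain phenotypes as a flat CSV
(strain, parameter, value, lower, upper, unit). Bounds are 95% confidence
intervals, mean ± 2 SEM, so `sem_from_bounds()` divides the interval width
by 4. The lysine release rate of A-L+ appears as a table over the
hypoxanthine concentration $H$ it experienced (from starvation, $H = 0$, to
a 4-h doubling, $H = 1.07$ µM); `cosmo_table_release_law()` interpolates it
piecewise-linearly with clamping at the ends.

Two release-law representations coexist deliberately. The linear law in
growth rate is the natural analytical form (growth rate is the bookkeeping
variable of the steady-state balance); the $H$-table is the natural spatial
form (each location knows its local hypoxanthine concentration but not a
global growth rate). Both describe the same measurements over the
community-relevant range of doubling times. The regression coefficients of
the linear law are consumed as published rather than re-derived, since the
underlying per-chemostat scatter is not part of the registry.

`propagate_error()` applies the variance formula
$s_g^2 = \sum_i (\partial g/\partial x_i)^2 s_i^2$ with analytic partials of
the approximate closed form, evaluated at the registry values with the
lysine release rate fixed at the 7-h-doubling chemostat row (0.78 ± 0.04
SEM) — the environment closest to the community's own doubling time. The
propagated error is 0.004/h, i.e. a 95% interval of ±0.01/h. Error
propagation deliberately uses the fixed-release form rather than the
variable-release quadratic, which keeps the partials analytic and matches
how the measurement uncertainties were defined. A caveat worth recording:
the registry stores bounds as printed (rounded), and for the two
consumption parameters the published per-term contributions back-compute to
slightly larger SEMs than the rounded bounds imply; the tests therefore
compare those two terms with a relaxed tolerance. The total is insensitive
to this (it agrees at the reported one significant figure, and with a
50,000-draw Monte-Carlo within 5%).

## Chemostat estimators

`simulate_chemostat()` integrates the single-strain chemostat (birth, death,
dilution, supply, consumption, release) with `deSolve` (lsoda, rtol 1e-8);
at steady state net growth equals the dilution rate. The estimators follow
directly from the balances:

* consumption per birth: $(S_0 - S_{ss})\,dil/(b\,N_{ss})$, with the
  approximation $S_0/N_{ss}$ when the vessel concentration is far below the
  reservoir's (`estimate_consumption_ss()` returns both);
* death rate: $dil \cdot \mathrm{dead}_{ss}/\mathrm{live}_{ss}$;
* release rate: $dil \cdot M_{ss}/\mathrm{live}_{ss}$.

The regression estimators use the whole time course: multiplying the
release (or death) balance by $e^{dil\,t}$ turns it into a straight line of
the exponentially weighted running integral of live density, computed by
the composite trapezoid rule (`exp_weighted_integral()`). The release
regression is constrained through the origin (released metabolite starts at
zero); the death regression keeps a free intercept (the initial dead pool).
Ordinary least squares is used throughout; on converged noiseless series
the steady-state and regression estimators agree within a few percent, and
the regression versions are preferred because they also use
pre-steady-state data.

Batch-culture estimators round out the set: consumption from the slope of
metabolite against density in exponential cultures (points after the
metabolite falls below a 10-µM assay floor are dropped, with a warning,
rather than silently), consumption from saturation yields (1/slope of a
through-origin regression), the detection-limit upper bound on release in
excess metabolite ($r = g M(T)/N(T)$, valid once $N(T) \gg N(0)$), and the
batch death rate from the dead/live ratio of an exponential culture.

## Live versus death-triggered release

Whether a metabolite is leaked by living cells or liberated upon death
changes how a community responds to evolution of the death rate, so
`compare_release_models()` fits both candidate models to starvation data:
metabolite against time-integrated live density (through the origin; slope
= fmole/cell/h) and metabolite against dead density (free intercept; slope
= fmole per death). Each fit reports an $R^2$ linearity metric — computed
about zero for the origin-constrained model — and the better-supported mode
is flagged.

Identifiability has a sharp structural limit. With a constant death rate,
no dilution and no initial dead pool, the dead density is *exactly*
proportional to the integrated live density, so the two models are
mathematically confounded; similarly, in a chemostat, live release at rate
$r$ and death release at $r/d$ per death produce identical metabolite
dynamics. The function therefore reports `"indeterminate"` whenever the
$R^2$ gap falls below 0.02, a threshold chosen so that the confounded cases
(gaps at numerical-noise level, or a few times $10^{-3}$ for
dilution-corrected chemostat transients) read as ties while structurally
identified starvation series (gaps of order 0.1) do not. For chemostat data
the optional `dil` argument applies the $e^{dil\,t}$ correction to all
variables first; without it the comparison would be biased by washout
rather than informative.

## Synthetic data and what passing tests show

`generate_chemostat_series()`, `generate_starvation_series()` and
`generate_cosmo_trajectory()` wrap the forward models and add multiplicative
lognormal measurement noise, mean-preserving, independent across time
points and channels, with default CVs of 7.5% for densities (mid-range of
the 5–10% flow-cytometry triplicate CV) and 10% for metabolite assays.
Noise-correlation structure across channels is unreported for the real
assays; independence is assumed and stated here. All generators are
deterministic under a fixed seed, which is recorded in the output
attributes.

Two generator choices deserve explanation:

* **Two-phase starvation death.** The starvation generator defaults to a
  death rate that is slow early (0.003/h to 12 h) and faster late (0.02/h),
  with a 5% initial dead pool — the qualitative kinetics observed for
  starving auxotrophs. This is not cosmetic: with a constant death rate the
  live- and dead-release hypotheses are confounded (see above), and no
  estimator could be validated against the generator. A scalar `death`
  argument restores the constant-rate special cases (e.g. zero death makes
  live-mode metabolite exactly linear in $N_0 t$).
* **Dilution as bookkeeping.** The community-trajectory generator treats
  periodic dilution as an observational event: raw densities are the latent
  undiluted trajectory divided by the cumulative dilution factor, and
  `accumulate_densities()` inverts this exactly. Simulating dilution as a
  physical division of cells *and* exchanged metabolites would stall growth
  for hours after each event under the steep Moser cooperativity
  ($n_L = 3.2$), because the model omits the intracellular metabolite
  stores that buffer real cells through such dips. The bookkeeping reading
  matches how accumulative densities are actually computed from serial
  dilutions.

What the synthetic suite shows, therefore, is estimator correctness under
the model's own assumptions (constant phenotypes, lognormal noise,
independent channels) — parameter recovery within 2% noiseless and unbiased
at realistic noise, release-mode selection in ≥95% of seeded series. It
does not show robustness to features real data have and the generator does
not: time-varying release during deep starvation, lag-phase physiology,
evolving phenotype mixtures, or correlated assay errors.

## Evolution dynamics

Mutant accumulation is modelled with conversion at a per-birth probability
$\mu$ (a fraction $\mu$ of ancestor births yield mutants), the only
formulation consistent with continuous-time dynamics and a
chromosome-mis-segregation mechanism; the conversion term moves births
between genotype pools without creating cells. Batch dynamics after a
configurable lag (composition frozen during the lag) have closed-form
solutions; chemostat competition extends the single-strain chemostat with
two Moser laws sharing one limiting metabolite. `fitness_advantage_from_ratio()`
fits the log-ratio slope $\ln(E/A)(t)$, and two pieces of arithmetic —
back-extrapolated initial mutant frequency and the expected pre-existing
mutant count $2 N \mu_p$ — support order-of-magnitude reasoning about
whether early sweeps are explained by pre-existing mutants.

## Spatial simulation

`simulate_spatial()` represents a community on an agarose column: metabolite
fields diffuse in 3-D (explicit 7-point stencil, no-flux boundaries), while
biomass occupies the surface layer of grid elements and reacts with its
local voxel — Moser birth on the local metabolite, consumption per birth,
release per cell-hour, with the lysine release rate interpolated from the
$H$-table at the local hypoxanthine concentration. Continuum biomass
densities replace the original individual-based cells; since release and
consumption scale linearly with biomass, the continuum limit is equivalent
for growth-rate questions (cell-scale patch statistics are out of scope,
and this surrogate is validated only against growth-rate and
metabolite-uniformity behaviour, not patch structure). Two diffusion
coefficients are supported (360 µm²/s in agarose, 20 µm²/s inside the cell
layer) or a single one; the predicted growth rate is insensitive to the
choice.

Numerics: operator-split explicit stepping with
$dt \le 0.9 / \left(2 D_{max} (2/dx^2 + 1/dz^2)\right)$; a configured step
above the stability limit is rejected before running, and when diffusion is
absent the step is capped at 0.002 h for reaction accuracy. Heterogeneous
diffusion uses face-averaged coefficients in flux form, so the diffusion
operator conserves mass exactly; total metabolite changes only by the
summed release-minus-consumption bookkeeping, which the result object
exposes. Metabolite fields are not clamped after reaction — transient
undershoots are left to relax (birth laws evaluate concentrations clamped
at zero) so that the mass ledger stays exact.

Problem sizes: the default domain is 160 × 160 µm laterally at 20-µm
spacing over a 5-mm agarose depth at 0.5-mm vertical spacing — deliberately
desk-scale; the unit tests use still smaller domains, and plate-scale
geometry (hundreds of µm at 5-µm spacing, 3-cm depth) remains configurable.
The reduced scale is justified by the model's own behaviour: metabolite
concentrations inside the community and in the agarose converge (within
~10%), so the steady-state growth rate matches the well-mixed prediction
(within 10% of 0.10/h) and is insensitive to domain size.

## Growth-rate fitting and window policy

`fit_growth_rate()` is an OLS slope of log total density against time. The
fitting window is the genuinely open design choice: plate experiments used
a 9×10⁷ total-cell onset cutoff in one place and a 1×10⁸ stationary-phase
exclusion in another, so both are exposed as options (`min_total`,
`max_total`) rather than hard-coded; for smooth simulated series an
automatic post-lag window starts where the instantaneous rate comes within
5% of the late-trajectory rate. With noisy data the automatic detector is
unreliable (finite-difference rates amplify noise) and an explicit window
should be given — the tests do exactly that.

## Known limitations

* Lag-phase dynamics are not quantitatively reproduced — starvation
  phenotypes are time-dependent in ways the constant-parameter model does
  not capture; predictions concern the post-lag steady state.
* Time-varying starvation release (slow, then speeding up) is not modelled;
  like the source measurements, a single rate over the assay window is
  assumed.
* The registry stores printed (rounded) values; uncertainties inherit that
  rounding.
* The spatial model is a continuum surrogate of an individual-based
  original; patch geometry and strain intermixing statistics are outside
  its validated scope.
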