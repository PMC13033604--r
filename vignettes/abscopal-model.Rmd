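---
title: "Modelling radiotherapy-induced abscopal tumor responses with abscopalQSP"
author: "abscopalQSP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling radiotherapy-induced abscopal tumor responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(abscopalQSP)
```

## The model

abscopalQSP simulates how irradiating one tumor can slow the growth of a
second, non-irradiated tumor in the same animal — the abscopal effect — by
tracking the whole-body journey of the immune cells that mediate it.

The scaffold is a physiologically based pharmacokinetic (PBPK) compartment
network of the mouse: ten organs (lungs, liver, gastrointestinal tract,
spleen, heart, kidneys, skin, muscle, bone, lymph nodes) plus two
subcutaneous tumors, each split into a vascular and an interstitial
sub-compartment, joined in the standard series circuit by arterial and
venous blood pools (venous blood feeds the lungs, the lungs feed arterial
blood, arterial blood perfuses all tissues in parallel).  Six immune
populations circulate through this network — dendritic cells (DC), M1 and
M2 macrophages, regulatory T cells, effector CD8+ T cells (TE1), and
antigen-presenting cells (APC) — moving with plasma flow between blood and
tissue vascular spaces, extravasating into interstitia at per-species rate
constants, and returning through the lymphatics: every tissue's
interstitial lymph drains to the lymph-node compartment, whose efferent
lymph re-enters venous blood.  Naive CD8+ T cells (TN) reside only in the
lymph nodes; viable and dead tumor cells (TV, TD) only in the two tumor
interstitia.  The state vector holds absolute cell counts per (species,
compartment, sub-compartment) — 161 states — so conservation checks are
exact, and concentrations are derived as count over sub-compartment volume.

On this scaffold sits the quantitative systems pharmacology (QSP) core, the
tumor–immune interaction kernel acting in the tumor interstitia and the
lymph nodes:

* viable tumor cells proliferate exponentially at the intrinsic rate
  `lg_tumor`;
* effector CD8+ cells kill tumor cells by mass action,
  `k_rc1 * C_TE1 * TV`, down-modulated by a saturating suppression
  denominator `1 + s_Treg C_Treg + s_M2 C_M2`; killed cells move to the
  dead-cell pool (conversion, not disappearance);
* DCs (and APCs, which share DC rate constants) and M1 macrophages
  phagocytose viable cells (`Ac_DC`, `Ac_M1`) and dead-cell debris
  (`Ac_dead_DC`, `Ac_dead_M1`); each engulfment converts the phagocyte into
  an APC, conserving DC+APC and M1+APC at the instant of conversion;
* debris is additionally cleared at `Clear_c_dead`;
* APCs migrate preferentially through the lymphatics to the lymph nodes,
  where they activate naive CD8+ cells at `k_TN * C_APC * TN`; the naive
  pool regenerates logistically towards its baseline `TN0` at `k_prol_TN`,
  and each activated naive cell yields `N_exp` effector cells (clonal
  expansion) that egress through the efferent lymph and home to both
  tumors.

Radiotherapy enters as instantaneous linear-quadratic (LQ) dose events: a
dose `D` to tumor 1 moves the fraction `1 - exp(-(a_c D + b_c D^2))` of
viable cells into the dead pool (mass-conserving, which is what fuels the
antigen cascade), and a dose to the lymph nodes depletes the node's APC,
TN and TE1 populations by the immune LQ survival `exp(-(a_IM D + b_IM
D^2))`; those cells leave the system.  The three study arms are no
treatment (CONTROL), 10 Gy to tumor 1 on day 10 (T1_RT), and additionally
3 Gy to the draining lymph nodes on days 10, 13 and 16 (T1_RT_LN_RT).
Only `k_TN` and `k_rc1` differ between the control and radiotherapy-treated
conditions (radiation-enhanced priming and effector quality); every other
parameter is shared across arms and enforced so by the parameter type.

```{r protocols}
build_protocol("T1_RT_LN_RT")
```

## Assumptions and committed functional forms

The kernel forms above — bilinear mass action, a saturating suppression
denominator, logistic naive-pool regeneration, exponential intrinsic
growth — are the package's committed defaults.  They are the simplest
forms consistent with the qualitative biology the model encodes, and they
are deliberately isolated behind the kernel functions (`cytolysis_rate`,
`phagocytosis_rates`, `ln_priming_rates`, `debris_clearance`) plus one
compiled right-hand side, so an alternative kernel can replace them without
touching the integration engine.  Other structural commitments:

* **Tumor volume** is carried by the cell pools, `V = (TV + TD) * v_cell`
  with `v_cell = 1e-6 mm3` (1e6 cells per mm3); dead cells occupy volume
  until cleared, so debris clearance shrinks the tumor.  Tumor sub-volumes
  scale with the instantaneous volume (interstitial fraction 0.5, vascular
  fraction 0.07), so intratumoral concentrations dilute as tumors grow.
* **Baseline immunity**: before day 0 the tumor-free trafficking system is
  linear, so its steady state is computed exactly by one linear solve per
  species (naive cells at `TN0`, APCs at zero) rather than by long
  pre-integration; both tumors are then implanted at `Vi_tumor0`.
  Implantation re-routes the small tumor share of arterial outflow
  (0.9% of cardiac output), so organ pools relax slightly after day 0 —
  a deliberate, physical transient.
* **Cell conservation in transport**: vascular convection uses the full
  regional plasma flow in and out of each tissue, and lymphatic return is
  carried by per-species interstitial exit rate constants; the physiology
  table still records the plasma balance (venous return `Q - L`) and is
  validated against it exactly.
* **No radiotherapy effects on vasculature**, no cytokine network, no
  memory T cells, no checkpoint pharmacology, no spatial or hypoxic
  substructure: all outside the model's scope.

## Parameters, units and the shipped defaults

All rates are per day, volumes in mm3 (1 mm3 = 1e-3 mL), interaction
constants per (cells/mL) per day, radiosensitivities in 1/Gy and 1/Gy2.
The shipped defaults (`default_parameters()`) are the package's calibrated
operating point for a fast-growing bilateral-flank melanoma:

```{r params}
default_parameters()
```

Choices worth explaining:

* `lg_tumor = 0.2/day`, `Vi_tumor0 = 25 mm3`: a control tumor implanted at
  25 mm3 reaches ~3000 mm3 by day 24, the familiar B16-scale trajectory.
* `a_c = 0.25/Gy`, `b_c = 0.025/Gy2` (alpha/beta = 10 Gy): a single 10 Gy
  fraction leaves `exp(-5)` (0.7%) of viable cells — a marked local
  regression.  `a_IM = 0.4/Gy`, `b_IM = 0.05/Gy2` make lymphocytes more
  radiosensitive: three 3 Gy nodal fractions deplete the node's T cells
  ~300-fold, the lever behind the blunted abscopal response under nodal
  irradiation.
* `k_prol_TN = 2/day`: the naive pool recovers from depletion in days.
  The activation rate is kept well below the regeneration rate in every
  arm (peak `k_TN * C_APC` is about 1e-3/day against `k_prol_TN = 2/day`),
  so the naive pool hugs `TN0` unless the node itself is irradiated; this
  is why naive-pool regeneration only becomes a sensitive parameter when
  the lymph nodes are in the radiation field, and it is the biologically
  expected regime (antigen-specific precursors are a tiny pool fraction).
  Correspondingly the clonal expansion factor `N_exp = 9000` (about 13
  doublings, mid-range for CD8 clonal bursts) carries the effector output.
* Tumor extravasation rate constants are uniformly low (0.15/day against
  0.3-1/day in organs), encoding the restricted permeability of abnormal
  tumor vasculature; this is why intratumoral CD8+ levels are similar in
  the irradiated and non-irradiated tumor even when systemic activation is
  strong.
* Physiology: a ~25 g mouse (plasma cardiac output 11 L/day, organ volumes
  and regional flow fractions from standard murine PBPK compilations),
  lymph flow 0.2% of regional plasma flow; all values live in one
  validated table (`build_default_physiology()`) serialisable as CSV or
  YAML.

## Numerics

The 161-state system is stiff (blood pools turn over in ~10 seconds while
tumors evolve over weeks), so the engine integrates with a BDF method
(`lsode`) at relative tolerance 1e-6 and per-state absolute tolerance
`1e-6 * (initial whole-body total of the species + 1)`, which respects the
many orders of magnitude spanned by the counts.  Dose events stop the
integrator, transform the state, and restart it, making the per-fraction
LQ survival exact by construction; the stored grid value at an event time
is the pre-dose state and both snapshots are kept in the trajectory.  The
output grid is uniform at 0.25 days and every time integral downstream
(TotVar, inter-group differences) is a trapezoid rule on that grid, so the
statistics are exactly reproducible from stored trajectories.  Stiff
solvers can undershoot zero: states above `-10 * atol` are clamped to
zero, anything more negative is an error (a silent large clamp would mask
model bugs).  A verified analytic Jacobian of the full system is compiled
in as well; the internally generated one is used by default as it is
marginally faster at this size.  The compiled right-hand side is tested
against an independent reference implementation in R to 1e-12 relative,
and two solver/tolerance combinations agree to 0.5% on tumor volumes.

Tumor sub-volumes are guarded below by 1e-9 mL so concentrations stay
finite if a tumor is eradicated.

## Calibration

`fit_abscopal()` (front end over `fit_ga()`) minimises, in log-parameter
space, the sum of squared errors between model and data on two observables:
tumor-volume time series, and empirical growth rates obtained by central
differences of the measurements (one-sided at the endpoints; the simulated
curve is linearly interpolated from the 0.25-day grid to the measurement
days and differenced identically).  The growth term's weight defaults to
the ratio of control-group data variances of the two observables, making
the terms commensurate; it is exposed as `weight_growth`.  All arms are
fitted jointly with shared parameters and the two-pair `k_TN`/`k_rc1`
structure — 16 log-parameters in total.

The optimiser is a real-coded genetic algorithm: tournament selection,
blend crossover, annealed Gaussian mutation, elitism, a stall-based
stopping rule, and (as is common practice for population searches) a
derivative-free/quasi-Newton local polish of the incumbent — periodically
during the run and once at the end — all behind `ga_config()`.  Search
bounds are drawn per run by expanding the initial population's column
ranges by up to 10% of their log-space magnitude (uniform draw per
parameter), so restarts are never trapped at preset bounds while remaining
anchored to the population.  Fixed seeds make every fit reproducible.

Uncertainty comes from `bootstrap_refit()`: whole subject-tumor curves are
resampled with replacement within each (group, tumor) stratum — stratum
sizes preserved exactly — and the model is refitted per replicate, each
refit's initial population holding the baseline optimum and all previous
bootstrap optima.  The resulting optima are the *baselines* for the
sensitivity and correlation analyses, and `summarize_ensemble()` turns
their trajectories into median and 90% interval bands.

On identifiability: with volume-only data the objective has sloppy
directions — most visibly `Ac_DC` against the other phagocytosis constants
and `k_TN` against `k_rc1` (the data largely constrain their product).
The recovery experiment in the test suite therefore scores the pooled
median relative error over the four headline parameters (`lg_tumor`,
`Ac_DC`, `k_TN`, `k_rc1` of the treated arms) across five GA seeds; single
parameters in a sloppy direction can individually sit further from the
truth at equal objective value.

## The synthetic cohort generator

`generate_cohort()` stands in for the calibration data (individual mouse
tumor-volume curves from a bilateral-flank melanoma experiment): three
arms, n = 8 mice per arm, two tumors per mouse, measurements every ~3 days
to day 24 plus the treatment day.  Each mouse draws lognormal perturbations
of `lg_tumor` and `Vi_tumor0` (sdlog 0.15 — inter-mouse variability), is
simulated under its arm's protocol, sampled at the measurement days, and
observed with multiplicative lognormal noise (sdlog 0.20, so errors scale
with tumor size and volumes stay positive; the level is chosen to match
the high variability typical of such experiments).  The generating truth
travels with the cohort as a JSON sidecar.  What the generator does *not*
emulate: cage effects, sacrifice rules, tumor-burden-dependent dropout,
digitisation error structure, or any deviation of the real biology from
this model family — so green calibration tests demonstrate that the
pipeline recovers parameters *within the model family*, not that the model
is true.

```{r cohort, eval = FALSE}
cohort <- generate_cohort(cohort_config(), seed = 11)
write_cohort(cohort, "cohort.csv")
```

## Sensitivity analysis: time-integrated total variance

For each bootstrap baseline `b` and parameter `j`, the parameter is scaled
one-at-a-time by the multipliers {10, 1.5, 1.1, 0.9, 0.5, 0.1} (two orders
of magnitude around the optimum) and each scaled set is simulated under
each arm.  For an output `V` (tumor volume, or the tumor's interstitial
CD8+ count) the dispersion of the sweep ensemble is summarised as

    TotVar_j^(b) = sum_i (1/T) Int_0^T (V_i(t) - Vbar(t))^2 dt

with `Vbar` the pointwise ensemble mean and `T = 24` days.  Within each
cell, per-bootstrap values are kept only if strictly greater than 10
(an absolute threshold in squared output units); the cell reports the
log10 of the mean retained value, or NaN if no replicate passed — the
machine-readable heatmap (`aggregate_totvar()`).  CD8+ levels enter as
absolute interstitial counts (densities per mL are computable from the
trajectory if wanted; counts are the default because the threshold is
absolute).  Median/IQR band summaries of the pooled sweep ensembles
(`median_iqr_bands()`) provide the trajectory-level view.

## Correlation analysis: stable Spearman associations

For a pair of arms (g1, g2), a parameter and an output, the time-averaged
inter-group difference at sweep level `i` and baseline `b` is

    dV_{g1-g2,i}^(b) = (1/T) Int_0^T (V_{g1,i}(t) - V_{g2,i}(t)) dt.

Per baseline, Spearman's rank correlation relates {dV_i} to the multiplier
levels (the multiplier's numeric value; any strictly monotone relabelling,
e.g. log multipliers, gives the identical rank correlation).  For n <= 8
levels the two-sided p-value is exact, by full enumeration of the n!
permutations with the inclusive tail `P(|rho_perm| >= |rho_obs|)` — a
perfect n = 6 monotone gives p = 2/720.  At n = 6 the exact null's
attainable significance level nearest 0.05 is 1/30, so uniformity of the
p-value under the null is checked in the suite at n = 8, where the
attainable level below 0.05 is 0.0458.  A cell is reported only when all
per-bootstrap correlations share one sign and at least 70% are significant
at 0.05 (`stability_filter()`); the reported value is the mean rho over
all replicates, annotated with the direction (+Δ/−Δ) of the mean
difference.  Cells with numerically constant differences (< 1e-12 spread)
are flagged "no-effect" rather than given an undefined correlation.  The
filter averages over all replicates once it passes (averaging only the
significant ones is a one-line variant).  No multiple-testing correction
is applied beyond the stability filter.

## Desk-scale study sizes

The full study design (50 bootstrap refits, all 14 parameters swept under
all arms) is available through `experiment_config()` defaults, but the
test suite and the reproduction script run desk-scale versions chosen as
the smallest sizes at which each qualitative conclusion is stable: B = 5
bootstrap baselines for the sensitivity/correlation pattern checks, GA
budgets of population 40 x 60 generations for recovery experiments and
population 10 x 5 generations for bootstrap refits, and the
four-parameter sweep set (`Ac_DC`, `k_rc1`, `k_TN`, `k_prol_TN`) the
analysis highlights.  Desk-scale bootstrap refits run the pure GA without
the local polish and are seeded at the shipped calibrated optimum (the
baseline optimum passed as initial population, as in the full procedure):
at this replicate budget a deep local polish merely overfits the resampled
noise and scatters the optima along the sloppy directions, whereas the
polish-free refits keep them in the tight cluster a full-budget bootstrap
produces, so the baseline-dependent qualitative patterns are evaluated at
parameter sets that genuinely reflect resampling variation.

## Known limitations

* The interaction kernel is a committed default, not a reconstruction of
  any particular published equation set; the kernel boundary is the
  intended extension point.
* Volume-only cohorts leave immune parameters partially confounded
  (product-type degeneracies); bootstrap spread reports that uncertainty
  but cannot remove it.
* Organ-level well-mixed compartments cannot represent intratumoral
  gradients, partial-volume irradiation or vascular remodelling.
* The mouse physiology table is a documented standard compilation, not a
  strain-specific measurement; human scaling is out of scope.
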