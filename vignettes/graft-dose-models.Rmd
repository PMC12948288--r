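---
title: "Dose models for intracerebral cell grafts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose models for intracerebral cell grafts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftkit)
```

## The two dose models

**Retention versus depth.** During withdrawal of an injection needle, cells
can reflux up the track; tissue viscosity seals the track with a force
assumed to grow with insertion depth, `N(d) = k·d^n`. Treating the escape
probability as exponential in that force and lumping the scale constants
into one parameter gives the retained fraction

$$R(d) = 1 - e^{-\beta d^n}, \qquad n = 1 \text{ by default},$$

with `d` in mm from the tissue surface along the needle axis and `β` in
mm⁻¹ (mm⁻ⁿ for general `n`). `R(0) = 0`, `R` rises monotonically and
saturates at 100% asymptotically; a larger `β` means near-complete
retention at shallower depths. `β` lumps tissue mechanics, needle tip and
inner diameter, suspension properties and protocol, so it must be
re-estimated whenever any of these change — which is exactly what
`fit_retention()` does from a small calibration experiment.

**Hypoperfusion versus volume.** A freshly implanted cell mass has no
perfusion of its own; oxygen reaches it only by diffusion from surrounding
tissue. With the standard mono-exponential diffusion profile
$pO_2(L) = pO_{2,cap} e^{-L/\lambda}$ ($pO_{2,cap}$ = 50 mmHg, λ = 30 µm),
tension falls below the 5-mmHg critical-hypoxia threshold at
`diffusion_margin()` ≈ 69 µm. The model simplifies this to a fixed
oxygenated margin `m` = 100 µm — a deliberately generous shell consistent
with tension approaching critically low values beyond ≈100 µm in
metabolically active cortex. The two are kept distinct in the API: the
margin is a configurable parameter defaulting to 100 µm, and the
diffusion-derived distance is exposed separately, never silently
substituted.

For a spherical graft of radius `r`, everything deeper than `m` from the
surface is hypoperfused:

$$\mathrm{HypoR}(r) = \left(\frac{r-m}{r}\right)^3 \quad (r > m), \qquad
\mathrm{HypoR}(v) = \mathrm{HypoR}\!\left(r(v)\right),\;
r(v) = \left(\frac{3v}{4\pi}\right)^{1/3}.$$

`HypoR` is exactly 0 for `r ≤ m` (clamped, not a negative cube), continuous
at the threshold, strictly increasing beyond it, and approaches 1 for large
grafts. The volume form is implemented through the radius-form identity;
the package works internally in µm and µm³ with explicit converters
(`nl_to_um3()` and friends) because protocol units mix mm, µm, nL and µL
and implicit conversion is the main trap in this model. Early growth is
tied to hypoperfusion by

$$G(v) = G_{max}\,(1 - \mathrm{HypoR}(v))^{\gamma},$$

`G_max` the maximal fold-change of the viability readout over the assay
window and `γ` a dimensionless sensitivity exponent; `γ = 3` is the default
supported by the calibration data, with `γ ∈ {1, 2, 3}` and free-`γ`
compared by `model_selection_gamma()`. `G` is defined as total fold-change
(end/start) over the assay window, not per-day; users can rescale.

The graft is always treated as a perfect sphere; the in-gel calibration
experiments show larger volumes forming compact spherical masses, which is
the regime the model is meant for.

## Estimation

Both fits minimize unweighted least squares on the fraction/readout scale
(no weighting scheme is assumed). Numerics:

- **Single free parameter** (β; free γ with `G_max` profiled; free margin):
  the SSR is evaluated on a log-spaced bracket of 60 points across the
  bounds (β ∈ [0, 50] mm⁻¹, γ ∈ [10⁻³, 20], margin ∈ [1, 2000] µm) and the
  bracketing interval refined with golden-section/parabolic search
  (`stats::optimize`). The bracket-then-refine scheme guards against local
  minima without randomness; a unit test checks the optimum against an
  exhaustive grid search at step 10⁻⁴.
- **`G_max` is profiled analytically**: for fixed γ the model is linear in
  `G_max`, so its optimum is the least-squares projection, clipped to
  bounds. This makes the two-parameter growth fit a one-dimensional
  problem.
- **Degenerate designs** are reported, not guessed at: all depths/volumes
  identical is an ill-posed error; all volumes at or below `V_th` makes the
  growth model flat, so `G_max` is the mean readout and γ is returned `NA`
  with a `gamma_unidentifiable` flag; a free γ landing on its bound is
  flagged `gamma_at_bound`.
- **QC**: a logical `qc_pass` column is honored as-is; there is no
  automatic outlier rejection. Raw imaging signals (`value_kind =
  "signal"`) are converted to fractions by dividing by an explicit
  delivered-dose reference — either reference-group rows in the table or a
  `reference` argument — because the normalization of photon counts to
  retained fraction is assay-specific and should never be implicit.

**Uncertainty.** Confidence intervals are percentile intervals from a
nonparametric bootstrap that resamples sites (rows), stratified by
depth/volume group whenever every group has ≥ 2 rows so that resamples
preserve the experimental design; resampling is unstratified otherwise.
Quantiles use the canonical `(R+1)·α` order-statistic convention with
normal-quantile interpolation (the same convention as `boot::boot.ci`,
against which it is unit-tested). Resample refits start from the full-data
bracket; resamples that lose the second distinct depth fail, and more than
20% failures abort with a diagnostic rather than returning a quietly
shrunken interval. All resampling indices come from one seeded generator
owned by `fit_config()`; identical seed and data give bit-identical
intervals. With 1000 resamples of a 23-site design the nominal 95%
percentile interval covers the true β close to its nominal rate — a
simulation in the test suite measures coverage across 500 synthetic
calibration experiments at noise σ = 0.05; percentile intervals on designs
this small are known to sit near the lower edge of nominal coverage.

**Diagnostics.** `goodness_of_fit()` reports R² (about the observed mean;
`NA` rather than −∞ when the observations have zero variance with nonzero
residuals), MAE and RMSE in observation units. `residual_trend()` computes
the two-sided Spearman rank correlation of residuals against the design
variable with average ranks for ties; p-values use the exact permutation
distribution for n < 10 (the full n! permutations are enumerated and
cached) and the t approximation for n ≥ 10, covering the 4–27-site designs
these assays use. Residual variation below 10⁻⁸ — far below any measurable
fraction — is treated as numerically zero so that optimizer noise on a
perfect fit is never flagged as a trend. Model selection ranks candidate
exponents by RMSE, collapsing RMSE differences within floating tolerance so
that a fixed exponent that matches a free fit to optimizer noise outranks
it; among models whose residuals show no trend, the `preferred` flag marks
the fewest-free-parameters model, RMSE as tie-break. `sensitivity_sweep()`
scales each parameter through ±20% by default, the conventional robustness
check for these fits.

## Planner conventions

`pulse_elevation_schedule()` splits the dose into equal boluses at linearly
spaced depths from deep to shallow (matching the reference protocol's
0.1-mm increments); when the total volume does not divide evenly, the
remainder goes to the deepest step, where predicted retention is highest.
Step volumes always sum to the total within 10⁻⁹ nL. `plan_report()`
predicts per-step retention `R(dᵢ)` and aggregates as the volume-weighted
mean Σ(vᵢ/V)·R(dᵢ); this is a first-order estimate that ignores
interactions between boluses (each bolus is assumed retained according to
its own deposition depth), and is labelled a model-based estimate in
output. The hypoperfusion prediction applies to the total delivered volume,
assuming the deposits coalesce into one mass. The aggregate is not
calibrated against in-vivo pulse-elevation outcomes; it is a planning aid,
not a validated effect size.

## Graft-interface analytics

Proximity to the implantation site uses planar (x, y) distance with an
inclusive boundary at the default 120-µm radius, because classification is
done on 2D projections of the imaging volume. Migration metrics are
computed in 3D: path length is the sum of per-session Euclidean steps and
net displacement the first-to-last distance, so path ≥ net always (triangle
inequality), with equality only for collinear motion. ROI calcium traces
are background-subtracted; negative corrected intensities are clipped to 0
and flagged rather than propagated. Normalization divides by a baseline
that defaults to the final-day group mean — by the end of a typical 6-day
course the peri-graft signal has returned to near baseline, making the last
day a sensible reference — but the rule is an explicit parameter
(`"first_day_mean"` or a number) because no universal convention exists.
`link_tracks()` is an opt-in greedy mutual-nearest-neighbour linker gated
by a maximum per-day step, deterministic with distance-then-id tie-breaks
and an ambiguity flag when alternatives were in gate; curated identities,
when present, should be used verbatim instead.

## What the synthetic generators emulate — and what they do not

`simulate_retention()` reproduces the depth-calibration design: depths
0.5/1.5/3.0 mm with 7/8/8 replicate sites plus a 4-site delivered-dose
reference group. Default noise is additive Gaussian on the fraction scale
(σ = 0.05) with clamping to [0, 1]; the clamped-row count is attached so
fitters can detect boundary pile-up. Lognormal multiplicative noise is
offered as an alternative because photon-count signals are heavy-tailed.
`simulate_growth()` reproduces the volume design (0.1/0.25/0.5/1.0 µL with
8/7/4/4 sites) with lognormal noise (σ_log = 0.15) keeping readouts
positive; the default `g_max_true = 2` represents a doubling of the
viability signal over the assay window, a typical magnitude for
proliferating neural stem cells in gel culture.

`simulate_graft_scene()` generates six-day interface dynamics: static
neurons inside (n = 10) and outside (n = 8) the 120-µm region with
corrected-intensity multipliers peaking on day 1–2 and returning to ≈1 by
day 4–5; and 20 microglia whose in-region occupancy follows a recruitment
probability peaking on days 2–3, moving with lognormal step lengths
(median 8 µm/day) and per-cell lognormal motility heterogeneity, since
observed microglial motility varies strongly cell to cell. With
`motility_scale = 0` cells freeze at their day-0 positions (occupancy then
stays at its day-0 state), the degenerate case used to test zero-path
tracks.

The generators deliberately do **not** emulate: bioluminescence physics
(optical depth, scattering, signal-to-cell-number calibration — synthetic
values are generated directly on the fraction/fold-change scale);
cell-concentration crowding effects; imaging segmentation or registration
error; session-to-session drift in the coordinate frame; or correlated
noise across sites. Passing parameter-recovery tests on these data
therefore demonstrates that the estimation machinery is correct and
well-calibrated under the stated noise models, not that the models capture
every feature of real calibration data.

## Problem sizes and numerical tolerances

The test suite runs the designs above at their native sizes; the heavier
simulation studies use 500 synthetic datasets with 1000 bootstrap
resamples each for the coverage study, 200 replicates per noise level for
the estimator-consistency ladder (σ ∈ {0.1, 0.05, 0.01}), and 10⁵
Monte-Carlo points per radius for the uniform-sphere check of the
hypoperfusion formula at r ∈ {150, 300, 600} µm. Closed-form identities
are asserted to 10⁻⁹–10⁻¹² relative tolerance; noiseless parameter
recovery to 10⁻⁵–10⁻⁶; values quoted to 3–4 significant figures in
protocol documentation to 10⁻³.

## Known limitations

- The hypoperfusion model is purely geometric: no reaction–diffusion
  oxygen consumption, no Krogh-cylinder vascular geometry, no
  revascularization dynamics. It is a planning bound, tightest in the
  first days post-implantation.
- β and γ are assay-specific lumped parameters; transferring them across
  cell types, tissues or needle geometries without re-calibration is
  unsupported by the model's own rationale.
- The retention model ignores volume and rate effects on reflux; the
  growth model ignores crowding (cell concentration), which is known to
  matter at high densities but has no accepted functional form here.
- Aggregate retention of a multi-step plan is a volume-weighted
  extrapolation of the single-bolus model, not an empirically validated
  prediction.
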