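# graftkit

Quantitative dose modelling and interface analytics for intracerebral cell
transplantation.

When a cell suspension is injected into brain tissue (or a tissue-mimicking
gel), two dose parameters dominate the outcome. **Injection depth** controls
how many cells stay at the target instead of refluxing up the needle track:
the tissue seals the track with a force that grows with depth, so the
retained fraction follows a saturating exponential

```
R(d) = 1 − exp(−β·d)
```

with `d` the insertion depth in mm and `β` (per mm) a lumped parameter for
tissue mechanics, needle geometry and protocol. **Injected volume** controls
early graft hypoxia: modelling the graft as a sphere in which only an outer
shell of thickness `m` (default 100 µm, motivated by mono-exponential oxygen
diffusion `pO₂(L) = pO₂cap·e^(−L/λ)` with λ = 30 µm) is adequately
oxygenated, the hypoperfused fraction is

```
HypoR(r) = ((r − m)/r)³,   r = (3v/4π)^(1/3)
```

which is 0 up to the threshold volume `V_th = (4/3)πm³ ≈ 4.2 nL` and rises
toward 1 for large grafts; early growth then follows
`G(v) = Gmax·(1 − HypoR(v))^γ`.

graftkit is for experimentalists planning transplantation protocols and for
analysts fitting these models to calibration data. It provides:

- the geometry/oxygen primitives (`radius_from_volume()`,
  `po2_at_distance()`, `hypoperfused_fraction_volume()`,
  `threshold_volume()`, `diffusion_margin()`);
- the dose models and their analytic inverses (`retention_at_depth()`,
  `depth_for_retention()`, `growth_rate()`,
  `max_volume_for_hypoperfusion_budget()`);
- estimation: bounded nonlinear least squares (`fit_retention()`,
  `fit_growth()`) with site-resampled bootstrap percentile CIs,
  R²/MAE/RMSE, Spearman residual-trend diagnostics, growth-exponent model
  selection (`model_selection_gamma()`) and ±20% sensitivity sweeps
  (`sensitivity_sweep()`), with broom-style `tidy()`/`glance()`/`augment()`
  and `autoplot()` methods;
- planners, including pulse-elevation injection schedules
  (`pulse_elevation_schedule()`, `plan_report()`);
- graft-interface analytics for longitudinal two-photon data
  (`classify_proximity()`, `count_within_radius()`, `migration_metrics()`,
  `normalize_trace()`, `link_tracks()`);
- seeded synthetic-data generators emulating the agarose/hydrogel
  calibration experiments and the graft-interface imaging scenes
  (`simulate_retention()`, `simulate_growth()`, `simulate_graft_scene()`).

## Worked example

Simulate a depth-calibration experiment (depths 0.5/1.5/3.0 mm, replicate
sites 7/8/8 plus a 4-site delivered-dose reference group, Gaussian noise
σ = 0.05 on the fraction scale), fit the retention model, and plan a
pulse-elevation injection with the fitted β:

```r
library(graftkit)

obs <- simulate_retention(retention_sim_spec(beta_true = 0.24,
                                             sigma = 0.05, seed = 42))
fit <- fit_retention(obs, fit_config(n_boot = 1000, seed = 7))
fit
#> <graftkit_fit: retention model, 23 sites>
#>   beta    0.23463  [0.2112, 0.25808]
#>   R^2 0.8184 | MAE 0.04683 | RMSE 0.06295
#>   residual trend: rho -0.344 (p = 0.108)
```

The true β = 0.24 is recovered at 0.235 with a bootstrap 95% CI of
[0.211, 0.258]; the residual-trend test finds no significant depth
dependence (p = 0.108), so the single-exponential shape is adequate.

```r
plan <- pulse_elevation_schedule(100, 0.5, 0.1, 5) |>
  plan_report(retention_model(0.235))
plan
#> <injection_plan> 100 nL total, 5 step(s), 0.1 uL/min, final dwell 300 s
#> # A tibble: 5 × 5
#>    step depth_mm volume_nl pause_after_s retention
#>   <int>    <dbl>     <dbl>         <dbl>     <dbl>
#> 1     1      0.5        20            20    0.111
#> 2     2      0.4        20            20    0.0896
#> 3     3      0.3        20            20    0.0680
#> 4     4      0.2        20            20    0.0458
#> 5     5      0.1        20           300    0.0232
#> predicted (model-based estimate): aggregate retention 0.0675, HypoR of total 0.2781
```

A 100-nL dose keeps the predicted hypoperfused fraction at 0.278 — indeed
`max_volume_for_hypoperfusion_budget(0.278)` returns ≈100 nL — while the
per-step retention column quantifies how hard superficial delivery is at
these depths, the motivation for the pulse-elevation technique.

`autoplot(fit)`, `plot_sensitivity(sensitivity_sweep(fit))` and
`plot_graft_dynamics()` render the standard figures for fits, sweeps and
graft-interface time courses.

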