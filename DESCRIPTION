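Package: graftkit
Title: Dose Modelling and Interface Analytics for Intracerebral Cell Grafts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models for planning and analysing intracerebral cell
    transplantation. Implements the saturating-exponential retention-versus-depth
    model, the spherical-graft hypoperfusion-versus-volume model with its
    oxygen-diffusion rationale, bounded nonlinear least-squares estimation with
    site-resampled bootstrap confidence intervals, goodness-of-fit and residual
    diagnostics, growth-exponent model selection, inverse dose planners
    including pulse-elevation injection schedules, peri-graft calcium and
    microglia tracking metrics, and seeded synthetic-data generators that
    emulate the agarose/hydrogel calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
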