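Package: oefunnel
Title: Between-Hospital Outcome Variation via Hierarchical Survival Models and Funnel Plots
Version: 0.1.0
Authors@R:
    person("Maarten", "Visser", email = "maarten.visser@example.org",
           role = c("aut", "cre"))
Description: Provider profiling for surgical registries. Fits a Bayesian
    hierarchical piecewise-exponential (log-Poisson counting process)
    proportional-hazards model with hospital random effects, converts the fit
    into patient-level risk-standardized event probabilities at an average
    hospital, aggregates them into observed-to-expected (O/E) ratios per
    hospital, draws funnel plots with exact or interpolated Poisson control
    limits, and explores hospital characteristics (case volume, academic
    setting, biopsy percentage) with univariate logistic regression and
    fixed-effects hazard ratios. Includes a calibrated multi-hospital
    synthetic registry generator for validation with known ground truth.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
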