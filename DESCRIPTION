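Package: crfalls
Title: Competing Risks Prediction Models for Serious Falls in Primary Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for developing and externally validating clinical
    prediction models for serious falls (hospital admission or death from a
    fall) in patients with an indication for antihypertensive treatment,
    under the competing risk of death from other causes. Implements
    Fine-Gray subdistribution hazard model fitting with fractional
    polynomial covariate transforms and a Breslow-type baseline cumulative
    incidence, jackknife pseudo-values of the Aalen-Johansen cumulative
    incidence function (grouped by linear predictor), logit-link
    pseudo-value recalibration, multiple imputation by chained equations
    with Nelson-Aalen outcome covariates and Rubin's rules, per-practice
    external validation metrics (observed:expected ratio, Harrell's C,
    Royston's D and its R-squared) pooled by REML random-effects
    meta-analysis with prediction intervals, and decision-curve net-benefit
    analysis. A seeded synthetic primary-care cohort generator with a
    clustered Fine-Gray event process supports end-to-end simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    metafor,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    cmprsk,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
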