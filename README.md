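# crfalls

Development and external validation of competing-risks prediction models
for **serious falls** — hospital admission or death with a primary
diagnosis of a fall — in adults with an indication for antihypertensive
treatment. The package is aimed at prediction-model methodologists and
pharmacoepidemiologists working with clustered primary-care data, where
death from other causes competes with the event of interest and follow-up
is heavily censored.

## What it implements

The risk of a fall by horizon *t* is modelled through a Fine–Gray
subdistribution hazard model,

F₁(t | x) = 1 − {1 − CIF₀(t)}^exp(xβ),

with fractional-polynomial transforms for continuous predictors, an
IPCW-weighted partial likelihood in which patients with a competing death
remain in later risk sets with weight Ĝ(t)/Ĝ(Tᵢ), and a Breslow-type
baseline cumulative incidence. Around that core:

* **Pseudo-value machinery** — Aalen–Johansen cumulative incidence and
  jackknife pseudo-values θᵢ = n F̂₁(t) − (n−1) F̂₁⁽⁻ⁱ⁾(t), computed in 50
  linear-predictor groups, used as censoring-consistent "observed
  outcomes" for calibration.
* **Recalibration** — per-horizon logit-link estimating-equation
  regression of pseudo-values on the original linear predictor (constant
  working variance; optional FP shape).
* **Multiple imputation** — chained equations with Nelson–Aalen outcome
  covariates, pooled by Rubin's rules.
* **External validation** — O:E ratio, Harrell's C, Royston's D and R²_D
  per general practice, pooled by REML random-effects meta-analysis with
  95% prediction intervals (log O:E / logit C / raw D scales).
* **Clinical utility** — decision-curve net benefit against treat-all and
  treat-none, and falls-versus-cardiovascular risk cross-classification
  at the 10% threshold.
* **Synthetic cohorts** — a seeded generator with clustered practices,
  realistic predictor marginals, missingness, and an exactly Fine–Gray
  event process with known true parameters, used by every simulation
  test.

See the methods vignette (`vignettes/falls-competing-risks.Rmd`) for the
statistical detail and design rationale.

## Worked example

```r
library(crfalls)

cohort  <- generate_cohort(sim_config(n_patients = 6000, n_practices = 40,
                                      seed = 42))
print(cohort)
#> Synthetic competing-risks cohort
#>   6000 patients in 40 practices; seed 42
#>   events: 216 falls, 428 competing deaths, 5356 censored
#>   cause-1 mass p = 0.0195, cause-2 rate = 0.0113

dev_pat <- impose_missingness(cohort$patients, seed = 43)
dev <- run_development(dev_pat, cohort$outcomes, horizons = c(5, 10),
                       recalibrate_horizons = 10, m = 2, cycles = 2,
                       n_groups = 50, seed = 44)
subset(dev$coef_table, term %in% c("sexfemale", "previous_falls",
                                   "opioid", "antidepressant"))
#>            term  shr shr_low shr_high
#>       sexfemale 1.34    1.01     1.78
#>  previous_falls 1.58    0.97     2.57
#>          opioid 1.59    1.21     2.10
#>  antidepressant 1.71    1.28     2.29
```

The subdistribution hazard ratios (`shr`) say, for example, that women
have a 34% higher subdistribution hazard of a serious fall than men at
fixed values of the other 23 predictors; at this cohort size (216 falls)
the rarest predictors are unstable, which is why the published analyses
this mirrors used millions of patients. Validating on a fresh cohort:

```r
val_ch <- generate_cohort(sim_config(n_patients = 8000, n_practices = 60,
                                     seed = 45))
val <- run_external_validation(dev, val_ch$patients, val_ch$outcomes,
                               horizons = 10, n_groups = 50, seed = 46)
val$horizons[["10"]]$meta$oe
#> OE pooled over 46 practices (log scale): 1.199 (95% CI 1.055 to 1.361)
#>   95% prediction interval 0.905 to 1.588; tau^2 = 0.0152

val$horizons[["10"]]$dca
#> Decision curve over 100 thresholds; pseudo-value prevalence 0.0382
#>   original dominates both comparators for thresholds 0.025-0.500
#>   recalibrated dominates both comparators for thresholds 0.030-0.500
#>   at the 10% threshold: net benefit original 0.0006, recalibrated 0.0006
```

A pooled O:E of 1.20 means observed falls incidence ran about 20% above
the model's predictions in this validation cohort (under-prediction);
the prediction interval describes the O:E expected in a *new* practice.
The decision curve shows the model yielding higher net benefit than
treating everyone or no one for any threshold above ~3%, including the
prespecified 10% falls-risk threshold.

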