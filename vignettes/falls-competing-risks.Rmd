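---
title: "Developing and validating a competing-risks falls prediction model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating a competing-risks falls prediction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crfalls` implements the full statistical workflow for building and
externally validating a clinical prediction model for *serious falls*
(hospital admission or death with a primary diagnosis of a fall) in adults
with an indication for antihypertensive treatment, where death from any
other cause is a competing event. This vignette explains the model, the
estimators, the synthetic cohort the package simulates, and the numerical
choices we made where the design was genuinely open.

## The model

The target of prediction is the cumulative incidence function (CIF) of a
fall by horizon $t$ (1, 5 or 10 years after the index date, which sits 12
months after cohort entry):

$$F_1(t \mid x) = \Pr(T \le t,\ \text{cause} = \text{fall} \mid x).$$

A Fine–Gray subdistribution hazard model links covariates to the CIF:

$$F_1(t \mid x) = 1 - \{1 - CIF_0(t)\}^{\exp(x\beta)},$$

where $\exp(\beta)$ are subdistribution hazard ratios (SHRs) and $CIF_0$
the baseline cumulative incidence at the covariate centering values.
Modelling the subdistribution — rather than the cause-specific hazard —
matters clinically: patients who die of other causes can no longer fall,
and ignoring that competing risk over-states the risk of falls, most
severely in frail older patients, exactly the group in whom an inflated
falls risk might wrongly discourage treatment.

Estimation (`fit_finegray()`) maximises the inverse-probability-of-
censoring-weighted (IPCW) partial likelihood: a patient with a competing
death at $T_i$ stays in later risk sets with weight
$w_i(t) = \hat G(t)/\hat G(T_i)$, where $\hat G$ is the Kaplan–Meier
estimate of the censoring distribution (`censoring_km()`, evaluated with
left limits so no patient self-weights). We route the heavy lifting
through the weighted risk-set expansion of `survival::finegray()` followed
by a weighted Cox partial likelihood (Newton–Raphson with step halving,
Breslow tie handling — consistent with the Breslow-type baseline
estimator), with robust standard errors clustered on patient. The baseline
cumulative subdistribution hazard is the Breslow estimator

$$\hat H_0(t) = \sum_{t_j \le t} \frac{d_j}{\sum_{i \in R(t_j)} w_i(t_j) e^{x_i\beta}},
\qquad CIF_0(t) = 1 - e^{-\hat H_0(t)},$$

evaluated at the training covariate means. Two identities anchor the
implementation in the tests: with no competing events the fit collapses to
an ordinary Cox model (coefficients agree to $10^{-6}$, baseline to
$10^{-8}$), and on general competing-risks data the coefficients agree
with the independent `cmprsk::crr` implementation.

### Functional form and diagnostics

Continuous predictors (age, cholesterol, frailty index) may enter through
fractional polynomials: FP1 powers from
$\{-2,-1,-0.5,0,0.5,1,2,3\}$ (0 meaning $\ln x$) and the 36 FP2 pairs,
with a repeated pair $(p,p)$ meaning $\{x^p, x^p\ln x\}$.
`select_fractional_polynomial()` scores every candidate by fitted
deviance, and prefers lower order wherever possible: FP2 must beat the
best FP1 by $\chi^2_{2,0.95}$ and FP1 must beat the linear term by
$\chi^2_{1,0.95}$, otherwise the simpler form is kept. Across multiply
imputed copies the per-copy winners are combined by majority vote, ties
broken toward lower order and then toward linearity. Variables with
non-positive support are shifted before transformation; the shift is
stored in the transform.

Proportional subdistribution hazards are checked by weighted Schoenfeld
residuals (`schoenfeld_residuals()`, computed in-package so that the
residuals sum exactly to the weighted score, i.e. to zero at the optimum)
correlated with event-time rank (`schoenfeld_check()`).

There is no automated variable selection: predictors with negligible
adjusted association are pruned only through the explicit `exclude`
argument, which is how systolic/diastolic blood pressure, BMI, activity
limitation, syncope and cataract are kept out of the default 24-predictor
model.

## Observed risks without censoring bias: pseudo-values

External calibration needs an individual-level "observed outcome" at a
fixed horizon, which censoring and competing death deny us. The package
uses jackknife pseudo-values of the Aalen–Johansen CIF:

$$\theta_i = n\,\hat F_1(t) - (n-1)\,\hat F_1^{(-i)}(t),$$

computed within 50 equal-count groups of the linear predictor
(`grouped_pseudovalues()`), for stability. Pseudo-values may fall outside
$[0,1]$; that is expected and they are never clipped. The efficient
implementation recomputes the leave-one-out estimate once per distinct
(time, event) class and matches brute-force leave-one-out recomputation
exactly (a $10^{-12}$ oracle test). Equal-count grouping was chosen over
equal-width because it guarantees stable group sizes in the skewed linear
predictor distributions these models produce; ties are broken by stable
patient order, groups that end up with fewer than two members are merged
with a neighbour, and a horizon beyond a group's last observed time is
truncated to that time with a warning.

## Recalibration

When calibration plots show miscalibration at a horizon, the model is
recalibrated by regressing the pseudo-values directly on the original
linear predictor through a logit-link mean with *constant* working
variance (`pseudo_glm()`): binomial variance would be wrong for responses
that can exit $[0,1]$, and the constant-variance estimating equations are
standard pseudo-observation practice. The solver is Gauss–Newton with
step halving; standard errors are working-independence sandwich
estimates. Optionally the shape of the recalibration map is chosen by the
same FP machinery (an F-test preference for simpler maps, since the
constant-variance quasi-deviance has an unknown scale). Only the
intercept and shape change — individual predictor coefficients are never
re-estimated. Recalibration is per-horizon and skippable: a horizon whose
apparent calibration is already good (typically 1 year) is simply left
out of `recalibrate_horizons`.

## Missing data

Cholesterol, ethnicity, deprivation quintile, smoking and alcohol are the
only imputable variables; absent diagnosis or prescription codes mean the
condition is absent, so flags are never imputed. `mice_impute()` runs
chained equations with, by default, 10 imputations and 10 cycles
(the cycle count is our choice; convergence can be monitored through the
returned per-cycle trace): stochastic Bayesian linear regression for
continuous variables (predictive-mean matching available where negative
draws would be implausible) and bootstrap multinomial logistic regression
for categorical ones. Every imputation model conditions on all model
covariates plus the Nelson–Aalen cumulative cause-specific hazards for
falls and death evaluated at the patient's own follow-up time, and the
two event indicators (`nelson_aalen_covariates()`), so that imputations
respect the competing-risks outcome. Coefficients and performance
metrics are pooled by Rubin's rules (`rubin_pool()`, with the classical
$(m-1)(1 + W/((1+1/m)B))^2$ degrees of freedom) on the scales used for
meta-analysis — log O:E, logit C, raw D — and by median/IQR where a
normal posterior cannot be assumed ($R^2_D$).

## Validation metrics and meta-analysis

Per practice and overall, `crfalls` computes, against the pseudo-values:

* **O:E ratio** — mean pseudo-value over mean predicted risk, with
  $SE(\ln O/E) = sd(\theta)/(O\sqrt n)$;
* **Harrell's C** — pairwise concordance over patient pairs with distinct
  pseudo-values, prediction ties counted one half (locked by an
  exhaustive-pair oracle test);
* **Royston's D** — the slope of the pseudo-value regression on the
  rankits of the linear predictor scaled by $\kappa = \sqrt{8/\pi}$, with
  $R^2_D = (D^2/\kappa^2)/(\pi^2/6 + D^2/\kappa^2)$;
* **calibration curves** — decile group means plus a local-linear loess
  smooth (fixed span 0.75; the span is cosmetic, the group points are
  smoother-independent).

Practices with fewer than 2 fall events or 20 patients are excluded from
pooling with a logged reason. `pool_metric()` pools across practices by
REML random-effects meta-analysis (`metafor::rma`, checked against a
restricted-likelihood grid search to $10^{-6}$) on the stated scales,
using the delta method $SE(\mathrm{logit}\,C) = SE(C)/\{C(1-C)\}$, and
reports 95% prediction intervals
$\hat\mu \pm t_{k-2,0.975}\sqrt{\hat\tau^2 + SE^2}$ (Higgins–Thompson) to
describe expected performance in a new practice. $\tau^2$ confidence
intervals, when requested, are profile-likelihood. The Knapp–Hartung
adjustment is available in `metafor` but off by default here, since the
analysis this package mirrors did not use it.

### A caution on C with pseudo-value outcomes

Defining C directly on pseudo-value ordering has a real consequence under
heavy censoring at low event rates: censored and competing-death patients
carry small pseudo-values whose *between-group* component scales like
minus the group CIF, so pairs of non-events are systematically slightly
discordant with predicted risk. With most pairs being non-event pairs,
this attenuates C substantially — it can sit below 0.5 even for a
genuinely discriminative model — whereas an indicator-based AUC (where
non-event pairs tie and drop out) would not. The definition here is the
documented, oracle-tested reading of "C applied to the pseudo-values";
treat its absolute level under heavy censoring with caution and lean on
D (which regresses rather than ranks) for separation.

## Decision-curve analysis

`net_benefit()` scores a treat-if-risk $\ge p_t$ policy as
$NB = \{TP - FP\,p_t/(1-p_t)\}/n$, with the event probability among the
treated estimated by the mean pseudo-value — keeping the utility analysis
consistent with the competing-risks framework rather than a naive
Kaplan–Meier. `decision_curve_analysis()` sweeps a grid (default 0.5%
steps over (0, 0.5]) against treat-all
($NB = \hat F - (1-\hat F)p_t/(1-p_t)$, exactly) and treat-none
($NB \equiv 0$), reports where each model variant dominates both, and
flags the prespecified 10% falls-risk threshold.
`cross_classify()` produces the 2×2 classification of falls risk against
an exogenous cardiovascular risk (e.g. from an established CVD
calculator — computing CVD risk is out of scope) at a shared threshold.

## The synthetic cohort generator

No real primary-care extract ships with the package; `generate_cohort()`
simulates cohorts with the statistical structure the analysis assumes,
with known truth so every estimator can be tested for recovery.

* **Covariates** emulate the descriptive statistics of large English
  primary-care cohorts indicated for antihypertensive treatment: age
  $\sim N(59.4, 13.2^2)$ truncated at 40; 52% women; systolic pressure
  $N(143.5, 11.9^2)$ confined to 130–179 mm Hg (the eligibility window);
  cholesterol $4.6 + 0.012\,\mathrm{age} + N(0, 1.05^2)$ mmol/L; a
  frailty index built as binomial deficits (out of 36) whose rate rises
  with age; and 16 comorbidity/prescription flags with published
  prevalences, most rising with age through logistic models whose
  intercepts are solved to hit the marginal prevalence exactly. The
  dependence structure (everything driven by age) is a documented choice,
  not a claim of fidelity to any real database, which publishes only
  marginals.
* **Events** follow the indirect subdistribution method: cause 1 with
  probability $1-(1-p)^{\exp(x\beta)}$ and conditional time from the
  closed-form inverse of
  $F_1(t\mid x) = 1 - \{1 - p(1-e^{-t})\}^{\exp(x\beta)}$; cause-2 times
  exponential. The truth is therefore *exactly* a Fine–Gray model,
  enabling exact parameter-recovery tests. $p$ and the cause-2 rate are
  tuned by numerical inversion so the 10-year CIFs hit their targets
  (defaults 3.5% falls, 10.3% competing death) under the realised
  covariates. True log-SHRs default to published adjusted effects, with a
  linear age effect of $\log(1.06)$ per 5 years.
* **Clustering**: log-normal practice sizes and a practice-level normal
  random intercept (SD 0.18) on the linear predictor, sized so the
  between-practice variance of log O:E is of the order seen in national
  validations ($\tau^2 \approx 0.03$).
* **Censoring**: exponential dropout (rate 0.03/year) plus staggered
  administrative censoring — uniform entry over a 21-year study window
  with follow-up capped at 10 years — giving median follow-up
  $\approx 6.6$ years (IQR $\approx$ 2.7–10). A point mass of censoring
  exactly at the horizon would be an artifact no calendar-bounded EHR
  cohort has, which is why entry is staggered; experiments that need
  controlled censoring set `entry_window = 0`.
* **Missingness** (`impose_missingness()`) is MAR through observed age
  and sex only, restricted to the five imputable variables, with marginal
  rates solved exactly (defaults mirror the published missingness:
  cholesterol 48.9%, ethnicity 56%, smoking 5%, alcohol 15%).

What passing tests on these cohorts do **not** show: robustness to
model misspecification (the truth is Fine–Gray by construction), to
informative censoring, to measurement error in covariates, or to the
joint covariate dependence of real EHR data.

## Numerical choices and degenerate inputs

* Ties: Breslow approximation throughout, matching the baseline
  estimator; quantile-group ties broken by stable patient order.
* `pseudo_glm()` declares failure (with the final step norm) rather than
  returning a stalled fit; ill-conditioned FP candidates in the
  recalibration search are dropped rather than allowed to abort it.
* Collinear covariates, all-censored cohorts, all-constant linear
  predictors, missing covariates at fit time, and empty outcome tables
  raise immediate, named errors.
* REML is run with a tightened convergence threshold ($10^{-10}$) so the
  $\tau^2$ grid-search oracle agrees to $10^{-6}$; $\hat\tau^2 = 0$ at
  the boundary whenever observed dispersion is within sampling noise.
* Model files are versioned JSON carrying coefficients, transforms,
  centering constants and the baseline CIF step grid, so externally
  published coefficient sets can be consumed by `read_model()` without
  code changes; the package ships only synthetic exemplars.

## Problem sizes

The test suite and the acceptance script run simulations at sizes chosen
to make Monte-Carlo error small relative to each tolerance while staying
desk-scale: parameter recovery and calibration-repair experiments at
$n = 20{,}000$; the end-to-end develop/validate pipeline at
$n = 12{,}000$ development patients (60 practices, 3 imputations) and
$n = 20{,}000$ validation patients (150 practices); oracle equivalence
checks on 100 random instances of $n \le 50$ each; meta-analysis recovery
with 200 practices. These sizes are the package's own choices and are
stated here so results can be reproduced exactly.

## Known limitations

* The C-statistic attenuation described above.
* No multilevel imputation by practice, no imputation of outcomes, no
  time-varying covariates or treatment changes during follow-up, no
  cause-2 model beyond what the IPCW weights require, and no
  cost-effectiveness layer behind the net-benefit analysis.
* Published model constants (the downloadable coefficient sets of the
  original falls algorithm) are not redistributed; `read_model()` can
  load them if obtained, and the package's own serialized models are
  synthetic exemplars.
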