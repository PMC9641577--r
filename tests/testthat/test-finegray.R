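test_that("censoring Kaplan-Meier matches the product-limit oracle", {
  none <- data.frame(time = 1:5, event = c(1, 2, 1, 1, 2))
  G <- censoring_km(none)
  expect_equal(G(c(0.5, 3, 10)), c(1, 1, 1))

  all_c <- data.frame(time = 1:4, event = rep(0L, 4))
  G2 <- censoring_km(all_c)
  expect_equal(G2(1), 3 / 4)
  expect_equal(G2(2), 3 / 4 * 2 / 3)
  expect_equal(G2(4), 0)

  set.seed(2)
  for (i in 1:20) {
    oc <- random_outcomes(sample(5:15, 1), gridded = TRUE)
    G3 <- censoring_km(oc)
    for (t in c(0.7, 1.9, 3.4))
      expect_equal(G3(t), oracle_censor_km(oc$time, oc$event, t),
                   tolerance = 1e-12)
  }
})

test_that("with zero competing events the fit equals a Cox model", {
  set.seed(3)
  for (i in 1:5) {
    n <- 150
    pat <- small_patients(n)
    oc <- data.frame(patient_id = 1:n,
                     time = rexp(n, 0.1 * exp(0.3 * pat$previous_falls)),
                     event = rbinom(n, 1, 0.7))
    m <- fit_finegray(pat, oc, predictors = small_predictors,
                      keep_fit = FALSE)
    X <- design_matrix(pat, predictors = small_predictors)
    cox <- survival::coxph(survival::Surv(oc$time, oc$event == 1) ~ X,
                           ties = "breslow")
    expect_equal(unname(m$coefficients), unname(coef(cox)),
                 tolerance = 1e-6)
    # Breslow baseline agrees at the centering covariates
    bh <- survival::basehaz(cox, centered = FALSE)
    H_oracle <- bh$hazard * exp(sum(colMeans(X) * coef(cox)))
    expect_equal(m$baseline$hazard,
                 H_oracle[match(m$baseline$time, bh$time)],
                 tolerance = 1e-8)
  }
})

test_that("estimates agree with an independent Fine-Gray implementation", {
  skip_if_not_installed("cmprsk")
  set.seed(4)
  n <- 600
  pat <- small_patients(n)
  X <- design_matrix(pat, predictors = small_predictors)
  lp <- drop(scale(X, scale = FALSE) %*% c(0.02, 0.3, 0.2, 0.4))
  oc <- sim_subdist_outcomes(lp, p = 0.35, cause2_rate = 0.05,
                             censor_rate = 0.05)
  m <- fit_finegray(pat, oc, predictors = small_predictors,
                    keep_fit = FALSE)
  crr <- cmprsk::crr(oc$time, oc$event, X, failcode = 1, cencode = 0)
  expect_equal(unname(m$coefficients), unname(crr$coef), tolerance = 1e-4)
})

test_that("parameter recovery on a simulated clustered cohort", {
  bt <- c(age = 0.012, sexfemale = log(1.25), cholesterol = 0.25)
  cfg <- sim_config(n_patients = 6000, n_practices = 1, practice_sd = 0,
                    beta_true = bt, target_cif1 = 0.45, target_cif2 = 0.1,
                    censor_rate = 0.02, entry_window = 0, seed = 12)
  ch <- generate_cohort(cfg)
  m <- suppressWarnings(
    fit_finegray(ch$patients, ch$outcomes,
                 predictors = c("age", "sex", "cholesterol"),
                 keep_fit = FALSE))
  z <- (m$coefficients[names(bt)] - bt) / m$se[names(bt)]
  expect_true(all(abs(z) < 3))
})

test_that("predicted cumulative incidence follows the model form", {
  fake <- structure(list(
    coefficients = c(x = log(2)), se = c(x = 0.1), vcov = NULL,
    transforms = NULL, center = c(x = 0),
    baseline = data.frame(time = c(1, 5, 10),
                          hazard = -log(1 - c(0.01, 0.05, 0.12)),
                          cif0 = c(0.01, 0.05, 0.12)),
    predictors = "x", n = 10, n_events = 5), class = "fg_model")
  expect_equal(predict_cif(fake, t = 5, lp = 0), 0.05)      # baseline case
  expect_equal(predict_cif(fake, t = 5, lp = log(2) / log(2) * 0),
               0.05)
  expect_equal(predict_cif(fake, t = 5, lp = log(2)), 1 - 0.95^2)
  expect_equal(predict_cif(fake, t = 0, lp = 1.7), 0)
  # monotone in t and in lp
  r_t <- predict_cif(fake, t = c(1, 5, 10), lp = 0.5)
  expect_true(all(diff(drop(r_t)) > 0))
  r_lp <- predict_cif(fake, t = 10, lp = c(-1, 0, 1))
  expect_true(all(diff(r_lp) > 0))
  expect_error(predict_cif(fake, t = -1, lp = 0), "non-negative")
})

test_that("a null covariate stays near a unit subdistribution hazard ratio", {
  bt <- c(age = 0.012)
  cfg <- sim_config(n_patients = 15000, n_practices = 1, practice_sd = 0,
                    beta_true = bt, target_cif1 = 0.5, target_cif2 = 0.1,
                    censor_rate = 0.02, entry_window = 0, seed = 13)
  ch <- generate_cohort(cfg)
  m <- suppressWarnings(
    fit_finegray(ch$patients, ch$outcomes,
                 predictors = c("age", "sex"),
                 keep_fit = FALSE))
  expect_gt(exp(m$coefficients["sexfemale"]), 0.95)
  expect_lt(exp(m$coefficients["sexfemale"]), 1.05)
})

test_that("fractional polynomial evaluation handles the log conventions", {
  fp <- fp_transform("age", c(0, 0))
  expect_equal(unname(fp_eval(exp(1), fp)[1, ]), c(1, 1))
  fp1 <- fp_transform("age", -0.5)
  expect_equal(unname(fp_eval(4, fp1)[1, 1]), 0.5)
  expect_error(fp_eval(-1, fp_transform("x", 2)), "shift")
  expect_error(fp_transform("x", c(1, 2, 3)), "length")
  expect_error(fp_transform("x", 1.7), "powers")
})

test_that("FP selection prefers the true functional form", {
  set.seed(6)
  hits_lin <- 0
  for (rep in 1:3) {
    n <- 1200
    pat <- data.frame(patient_id = 1:n, age = runif(n, 40, 90),
                      sex = sample(c("female", "male"), n, TRUE))
    X <- design_matrix(pat, predictors = c("age", "sex"))
    lp <- drop(scale(X, scale = FALSE) %*% c(0.03, 0.3))
    oc <- sim_subdist_outcomes(lp, p = 0.45, cause2_rate = 0.03,
                               censor_rate = 0.02)
    fp <- select_fractional_polynomial(pat, oc, "age",
                                       predictors = c("age", "sex"))
    if (identical(fp$powers, 1)) hits_lin <- hits_lin + 1
  }
  expect_gte(hits_lin, 2)  # linear truth recovered in most replicates

  # quadratic truth: chosen powers include 2
  n <- 3000
  pat <- data.frame(patient_id = 1:n, cholesterol = runif(n, 1, 3),
                    sex = sample(c("female", "male"), n, TRUE))
  lp2 <- 0.9 * (pat$cholesterol^2 - mean(pat$cholesterol^2))
  oc2 <- sim_subdist_outcomes(lp2, p = 0.45, cause2_rate = 0.03)
  fp2 <- select_fractional_polynomial(pat, oc2, "cholesterol",
                                      predictors = c("cholesterol", "sex"))
  expect_true(2 %in% fp2$powers)
})

test_that("Schoenfeld diagnostics: residuals centre at zero, power against TV effects", {
  set.seed(7)
  n <- 800
  pat <- small_patients(n)
  X <- design_matrix(pat, predictors = small_predictors)
  lp <- drop(scale(X, scale = FALSE) %*% c(0.02, 0.3, 0.2, 0.4))
  oc <- sim_subdist_outcomes(lp, p = 0.5, cause2_rate = 0.03,
                             censor_rate = 0.02)
  m <- fit_finegray(pat, oc, predictors = small_predictors)
  res <- schoenfeld_residuals(m)$residuals
  expect_true(all(abs(colSums(res)) < 1e-6 *
                    pmax(1, colSums(abs(res)))))
  sc <- schoenfeld_check(m)
  expect_equal(nrow(sc), length(m$coefficients))

  # strongly time-varying effect: crossing hazards by Weibull shapes
  flagged <- 0
  for (rep in 1:5) {
    x <- rbinom(n, 1, 0.5)
    tt <- ifelse(x == 1, rweibull(n, 0.5, 2), rweibull(n, 2.5, 2))
    pat2 <- data.frame(patient_id = 1:n, previous_falls = x)
    oc2 <- data.frame(patient_id = 1:n, time = pmin(tt, 10),
                      event = as.integer(tt <= 10))
    m2 <- fit_finegray(pat2, oc2, predictors = "previous_falls")
    if (schoenfeld_check(m2)$flag[1]) flagged <- flagged + 1
  }
  expect_gte(flagged, 4)
})

test_that("degenerate inputs raise informative errors", {
  pat <- small_patients(20)
  oc <- data.frame(patient_id = 1:20, time = rexp(20, 0.2) + 0.1,
                   event = rep(0L, 20))
  expect_error(fit_finegray(pat, oc, predictors = small_predictors),
               "cause-1 event")
  pat2 <- small_patients(60)
  pat2$dup <- pat2$previous_falls
  oc2 <- data.frame(patient_id = 1:60, time = rexp(60, 0.2) + 0.1,
                    event = rbinom(60, 1, 0.5))
  expect_error(fit_finegray(pat2, oc2,
                            predictors = c(small_predictors, "dup")),
               "collinear")
  pat3 <- small_patients(30)
  pat3$cholesterol[2] <- NA
  oc3 <- data.frame(patient_id = 1:30, time = rexp(30, 0.2) + 0.1,
                    event = rbinom(30, 1, 0.5))
  expect_error(fit_finegray(pat3, oc3,
                            predictors = small_predictors), "impute")
})
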