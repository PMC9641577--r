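test_that("Nelson-Aalen covariates match hand computation", {
  oc <- data.frame(patient_id = 1:3, time = c(1, 2, 3), event = c(1, 2, 0))
  na <- nelson_aalen_covariates(oc)
  expect_equal(na$na_fall, c(1/3, 1/3, 1/3))
  expect_equal(na$na_death, c(0, 1/2, 1/2))
  expect_equal(na$d_fall, c(1L, 0L, 0L))
  expect_equal(na$d_death, c(0L, 1L, 0L))

  none <- data.frame(patient_id = 1:4, time = 1:4, event = rep(0L, 4))
  na0 <- nelson_aalen_covariates(none)
  expect_true(all(na0$na_fall == 0) && all(na0$na_death == 0))

  n <- 7
  all1 <- data.frame(patient_id = 1:n, time = seq_len(n), event = rep(1L, n))
  na1 <- nelson_aalen_covariates(all1)
  expect_equal(na1$na_fall, cumsum(1 / (n - seq_len(n) + 1)))
  expect_error(nelson_aalen_covariates(
    data.frame(patient_id = 1, time = -1, event = 1)), "positive")
})

test_that("Rubin's rules reproduce the pooling formulas", {
  p <- rubin_pool(c(1, 2), c(0.5, 0.5))
  expect_equal(p$estimate, 1.5)
  expect_equal(p$W, 0.5)
  expect_equal(p$B, 0.5)
  expect_equal(p$T, 1.25)
  same <- rubin_pool(rep(3.3, 5), rep(0.2, 5))
  expect_equal(same$B, 0)
  expect_equal(same$T, same$W)
  expect_equal(same$estimate, 3.3)
  expect_equal(same$df, Inf)
  # T >= W always, and the classical df formula
  set.seed(1)
  for (i in 1:20) {
    m <- sample(2:8, 1)
    est <- rnorm(m); v <- rexp(m)
    p <- rubin_pool(est, v)
    expect_gte(p$T, p$W)
    if (p$B > 0)
      expect_equal(p$df, (m - 1) * (1 + p$W / ((1 + 1/m) * p$B))^2)
  }
  expect_error(rubin_pool(1, 1), "m >= 2")
})

test_that("median/IQR pooling uses order statistics", {
  expect_equal(median_iqr_pool(1:5)$median, 3)
  expect_equal(median_iqr_pool(rep(2, 6))$iqr, 0)
  expect_equal(median_iqr_pool(c(0.1, 0.4, 0.2, 0.9))$median, 0.3)
})

test_that("a complete cohort passes through imputation unchanged", {
  set.seed(10)
  ch <- generate_cohort(sim_config(n_patients = 300, n_practices = 3,
                                   seed = 10))
  st <- mice_impute(ch$patients, ch$outcomes, m = 3, seed = 1)
  expect_equal(st$m, 3)
  expect_identical(st$copies[[1]], ch$patients)
  expect_identical(st$copies[[2]], ch$patients)
})

test_that("MAR cholesterol imputation recovers the cholesterol-age slope", {
  ch <- generate_cohort(sim_config(n_patients = 3000, n_practices = 5,
                                   seed = 21))
  pm <- impose_missingness(ch$patients, rates = c(cholesterol = 0.48),
                           mar_strength = 0.4, seed = 3)
  st <- mice_impute(pm, ch$outcomes, m = 5, cycles = 3, seed = 7,
                    predictors = c("age", "sex", "cholesterol",
                                   "frailty_index"))
  expect_true(all(vapply(st$copies,
                         function(cp) !anyNA(cp$cholesterol), logical(1))))
  # observed cells untouched
  obs <- !is.na(pm$cholesterol)
  expect_identical(st$copies[[1]]$cholesterol[obs], pm$cholesterol[obs])
  fits <- lapply(st$copies, function(cp) {
    f <- lm(cholesterol ~ age, data = cp)
    c(coef(f)["age"], vcov(f)["age", "age"])
  })
  pooled <- rubin_pool(vapply(fits, `[`, numeric(1), 1),
                       vapply(fits, `[`, numeric(1), 2))
  # generator truth: cholesterol = 4.6 + 0.012 age + noise
  expect_lt(abs(pooled$estimate - 0.012), 3 * sqrt(pooled$T))
})

test_that("MCAR imputations match the observed distribution", {
  ch <- generate_cohort(sim_config(n_patients = 2000, n_practices = 4,
                                   seed = 31))
  pm <- impose_missingness(ch$patients, rates = c(cholesterol = 0.4),
                           mar_strength = 0, seed = 5)
  st <- mice_impute(pm, ch$outcomes, m = 3, cycles = 2, seed = 9,
                    predictors = c("age", "sex", "cholesterol"))
  mis <- is.na(pm$cholesterol)
  obs_mean <- mean(pm$cholesterol[!mis])
  obs_sd <- sd(pm$cholesterol[!mis])
  for (cp in st$copies)
    expect_lt(abs(mean(cp$cholesterol[mis]) - obs_mean), 0.5 * obs_sd)
})

test_that("categorical imputation draws valid levels and respects observed cells", {
  ch <- generate_cohort(sim_config(n_patients = 800, n_practices = 3,
                                   seed = 41))
  pm <- impose_missingness(ch$patients, rates = c(smoking = 0.3), seed = 2)
  st <- mice_impute(pm, ch$outcomes, m = 2, cycles = 2, seed = 11,
                    predictors = c("age", "sex", "smoking"))
  for (cp in st$copies) {
    expect_false(anyNA(cp$smoking))
    expect_true(all(cp$smoking %in% c("non", "former", "current")))
    obs <- !is.na(pm$smoking)
    expect_identical(cp$smoking[obs], pm$smoking[obs])
  }
})

test_that("fully missing variables are rejected", {
  ch <- generate_cohort(sim_config(n_patients = 50, n_practices = 2,
                                   seed = 51))
  p <- ch$patients
  p$cholesterol <- NA_real_
  expect_error(mice_impute(p, ch$outcomes, m = 2), "100% missing")
})
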