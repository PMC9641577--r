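test_that("same seed reproduces the cohort exactly, different seed does not", {
  cfg <- sim_config(n_patients = 500, n_practices = 5, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$outcomes, b$outcomes)
  cfg2 <- sim_config(n_patients = 500, n_practices = 5, seed = 43)
  expect_false(identical(generate_cohort(cfg2)$outcomes, a$outcomes))
})

test_that("null-effect uncensored simulation matches the closed-form subdistribution", {
  bt <- c(age = 0)
  cfg <- sim_config(n_patients = 50000, n_practices = 1, practice_sd = 0,
                    beta_true = bt, p = 0.05, cause2_rate = 0.01,
                    censor_rate = 0, entry_window = 0, seed = 5)
  ch <- generate_cohort(cfg)
  expected <- 0.05 * (1 - exp(-10))
  mc_se <- sqrt(expected * (1 - expected) / 50000)
  expect_lt(abs(mean(ch$outcomes$event == 1) - expected), 3 * mc_se)
})

test_that("tuned defaults reproduce the target 10-year incidences", {
  cfg <- sim_config(n_patients = 30000, censor_rate = 0,
                    entry_window = 0, seed = 8)
  ch <- generate_cohort(cfg)
  p1 <- mean(ch$outcomes$event == 1)
  p2 <- mean(ch$outcomes$event == 2)
  expect_lt(abs(p1 - 0.035), 3 * sqrt(0.035 * 0.965 / 30000))
  expect_lt(abs(p2 - 0.103), 3 * sqrt(0.103 * 0.897 / 30000))
})

test_that("predictor marginals track the configured population", {
  ch <- generate_cohort(sim_config(n_patients = 20000, seed = 3))
  p <- ch$patients
  expect_true(all(p$age >= 40))
  expect_lt(abs(mean(p$sex == "female") - 0.52), 0.015)
  expect_true(all(p$sbp >= 130 & p$sbp <= 179))
  expect_true(all(p$frailty_index >= 0 & p$frailty_index <= 1))
  expect_lt(abs(mean(p$previous_falls) - 0.06), 0.01)
  expect_true(all(p$imd_quintile %in% 1:5))
  # default follow-up tuning gives a median in the 6-7 year range
  expect_gt(median(ch$outcomes$time), 5.5)
  expect_lt(median(ch$outcomes$time), 7.5)
})

test_that("empirical cumulative incidence converges to the subdistribution", {
  bt <- c(sexfemale = 0.5)
  dist_at <- function(n) {
    cfg <- sim_config(n_patients = n, n_practices = 1, practice_sd = 0,
                      beta_true = bt, p = 0.2, cause2_rate = 0.02,
                      censor_rate = 0, entry_window = 0, seed = 9)
    ch <- generate_cohort(cfg)
    grid <- seq(0.5, 9.5, by = 0.5)
    idx <- ch$patients$sex == "female"
    emp <- vapply(grid, function(s)
      mean(ch$outcomes$time[idx] <= s & ch$outcomes$event[idx] == 1),
      numeric(1))
    max(abs(emp - subdistribution_cif(grid, 0.5, 0.2)))
  }
  expect_lt(dist_at(20000), dist_at(1000))
})

test_that("blood-pressure eligibility applies the stated rules", {
  bp <- data.frame(
    patient_id = c(1, 1, 1, 2, 2, 3),
    date = c(0, 1, 2, 0, 1, 0),
    sbp = c(125, 131, 140, 135, 182, 150))
  ages <- c(`1` = 50, `2` = 70, `3` = 39)
  res <- apply_eligibility(bp, ages)
  expect_equal(res$patient_id, "1")        # 2 excluded (>180), 3 under 40
  expect_equal(res$entry_date, 1)          # first qualifying reading (131)
  expect_equal(res$index_date, 2)          # entry + 12 months
  # order-independence and idempotence over patients
  res2 <- apply_eligibility(bp[sample(nrow(bp)), ], ages)
  expect_equal(res2[order(res2$patient_id), ], res[order(res$patient_id), ])
  expect_warning(apply_eligibility(bp, c(ages, `9` = 55)), "no readings")
})

test_that("missingness lands only on the imputable variables at the configured rates", {
  ch <- generate_cohort(sim_config(n_patients = 20000, seed = 4))
  p0 <- ch$patients
  expect_identical(impose_missingness(p0, rates = c(cholesterol = 0)), p0)
  pm <- impose_missingness(p0, rates = c(cholesterol = 0.48,
                                         smoking = 0.1), seed = 2)
  r <- mean(is.na(pm$cholesterol))
  expect_lt(abs(r - 0.48), 3 * sqrt(0.48 * 0.52 / 20000))
  expect_lt(abs(mean(is.na(pm$smoking)) - 0.1),
            3 * sqrt(0.1 * 0.9 / 20000))
  flags <- c("previous_falls", "stroke", "opioid", "antidepressant")
  expect_false(any(vapply(pm[flags], anyNA, logical(1))))
  expect_false(anyNA(pm$age))
  # MAR: missingness rises with age
  expect_gt(mean(p0$age[is.na(pm$cholesterol)]),
            mean(p0$age[!is.na(pm$cholesterol)]))
  expect_error(impose_missingness(p0, rates = c(cholesterol = 1)),
               "rates")
})
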