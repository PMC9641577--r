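test_that("observed:expected ratio arithmetic and invariances", {
  theta <- rep(0.10, 50)
  pred <- rep(0.05, 50)
  oe <- observed_expected_ratio(theta, pred)
  expect_equal(oe$oe, 2)
  set.seed(1)
  th <- rnorm(100, 0.2, 0.3)
  pr <- runif(100, 0.01, 0.4)
  a <- observed_expected_ratio(th, pr)
  perm <- sample(100)
  b <- observed_expected_ratio(th[perm], pr[perm])
  expect_equal(a$oe, b$oe)
  c3 <- observed_expected_ratio(th, 3 * pr)
  expect_equal(c3$E, 3 * a$E)
  expect_equal(c3$oe, a$oe / 3)
  expect_error(observed_expected_ratio(th, rep(0, 100)), "positive")
  expect_warning(observed_expected_ratio(rep(-0.1, 20), rep(0.1, 20)),
                 "excluded")
})

test_that("Harrell's C equals exhaustive pair enumeration", {
  # perfect ranking
  th <- c(0.1, 0.2, 0.5, 0.9)
  expect_equal(harrell_c(th, th)$c, 1)
  # the 4-patient worked case: the oracle fixes the value
  th4 <- c(0, 0, 1, 1)
  r4 <- c(0.1, 0.4, 0.3, 0.2)
  expect_equal(oracle_concordance(th4, r4), 0.5)
  expect_equal(harrell_c(th4, r4)$c, oracle_concordance(th4, r4))
  set.seed(2)
  for (i in 1:30) {
    n <- sample(4:25, 1)
    th <- sample(c(0, 0.5, 1), n, replace = TRUE) + rnorm(n, 0, 0.2)
    pr <- round(runif(n), 1)          # induces prediction ties
    expect_equal(harrell_c(th, pr)$c, oracle_concordance(th, pr),
                 tolerance = 1e-12)
  }
  expect_warning(cc <- harrell_c(c(0, 1, 0), rep(0.2, 3)), "identical")
  expect_equal(cc$c, 0.5)
})

test_that("C is invariant to strictly monotone transforms of predictions", {
  set.seed(3)
  th <- rnorm(200)
  pr <- runif(200)
  c1 <- harrell_c(th, pr)$c
  expect_equal(harrell_c(th, qlogis(pr))$c, c1, tolerance = 1e-12)
  expect_equal(harrell_c(th, pr^3)$c, c1, tolerance = 1e-12)
})

test_that("C on uninformative predictions is near one half", {
  set.seed(4)
  th <- rbinom(10000, 1, 0.2)
  pr <- runif(10000)
  expect_lt(abs(harrell_c(th, pr)$c - 0.5), 0.02)
})

test_that("Royston's D and its explained variation", {
  expect_equal(r2_from_d(0), 0)
  d <- 1.597
  r2_expected <- (d^2 / (8 / pi)) / (pi^2 / 6 + d^2 / (8 / pi))
  expect_equal(r2_from_d(d), r2_expected, tolerance = 1e-12)
  expect_equal(round(r2_expected, 3), 0.378)
  # strictly increasing in |D|, bounded in [0, 1)
  ds <- seq(0, 10, by = 0.25)
  expect_true(all(diff(r2_from_d(ds)) > 0))
  expect_true(all(r2_from_d(ds) >= 0 & r2_from_d(ds) < 1))

  set.seed(5)
  n <- 3000
  th <- rbinom(n, 1, 0.3)
  lp_null <- rnorm(n)
  dn <- royston_d(th, lp_null)
  expect_lt(abs(dn$d), 3 * dn$se)
  expect_lt(dn$r2, 0.02)
  expect_warning(d0 <- royston_d(th[1:50], rep(1, 50)), "constant")
  expect_equal(d0$d, 0)
  expect_error(royston_d(th[1:5], lp_null[1:5]), "at least 10")
})

test_that("D separates a genuinely prognostic linear predictor", {
  set.seed(6)
  n <- 4000
  lp <- rnorm(n)
  oc <- sim_subdist_outcomes(lp, p = 0.3, cause2_rate = 0.02)
  th <- jackknife_pseudovalues(oc, 10)
  dd <- royston_d(th, lp)
  expect_gt(dd$d, 0.5)
  expect_gt(dd$r2, 0.05)
})

test_that("calibration curve group points are smoother-independent", {
  set.seed(7)
  th <- rnorm(500, 0.2, 0.2)
  pr <- runif(500, 0.01, 0.5)
  c1 <- calibration_curve(th, pr, span = 0.75)
  c2 <- calibration_curve(th, pr, span = 0.4)
  expect_equal(c1$points, c2$points)
  expect_equal(nrow(c1$points), 10)
  expect_equal(sum(c1$points$n), 500)
  cc <- calibration_curve(th, rep(0.2, 500))
  expect_equal(nrow(cc$points), 1)
  expect_equal(cc$points$observed, mean(th))
  expect_error(calibration_curve(th, pr, n_groups = 501), "groups")
})

test_that("per-practice metrics: single practice equals overall, symmetry, exclusions", {
  set.seed(8)
  n <- 300
  pat <- small_patients(n)
  pat$practice_id <- 1
  oc <- sim_subdist_outcomes(rnorm(n), p = 0.3, cause2_rate = 0.02)
  th <- jackknife_pseudovalues(oc, 10)
  lp <- rnorm(n)
  pred <- plogis(lp - 2)
  pp <- per_practice_performance(pat, oc, th, pred, lp)
  expect_equal(nrow(pp), 1)
  expect_equal(pp$oe, observed_expected_ratio(th, pred)$oe)
  expect_equal(pp$c, harrell_c(th, pred)$c)
  expect_equal(pp$d, royston_d(th, lp)$d)

  # two identical practices give identical metric rows
  pat2 <- rbind(pat, transform(pat, patient_id = patient_id + n,
                               practice_id = 2))
  oc2 <- rbind(oc, transform(oc, patient_id = patient_id + n))
  pp2 <- per_practice_performance(pat2, oc2, c(th, th), c(pred, pred),
                                  c(lp, lp))
  expect_equal(pp2$oe[1], pp2$oe[2])
  expect_equal(pp2$c[1], pp2$c[2])
  expect_equal(pp2$d[1], pp2$d[2])

  # minimum-data rules
  pat$practice_id <- c(rep(1, 290), rep(2, 10))
  pp3 <- per_practice_performance(pat, oc, th, pred, lp)
  expect_true(pp3$excluded[pp3$practice_id == "2"])
  expect_match(pp3$reason[pp3$practice_id == "2"], "too few")
})
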