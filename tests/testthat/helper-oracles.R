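# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementations.

# Aalen-Johansen cause-1 CIF via survfit multi-state (product-limit)
oracle_aj <- function(time, event, t) {
  if (all(event == 0)) return(0)
  f <- factor(event, levels = 0:2, labels = c("cens", "e1", "e2"))
  # survfit warns (log of zero survival) on tiny degenerate subsets
  fit <- suppressWarnings(survival::survfit(survival::Surv(time, f) ~ 1))
  j <- which(colnames(fit$pstate) == "e1")
  sf <- stats::stepfun(fit$time, c(0, fit$pstate[, j]))
  sf(t)
}

# brute-force leave-one-out pseudo-values
oracle_jackknife <- function(time, event, t) {
  n <- length(time)
  full <- oracle_aj(time, event, t)
  loo <- vapply(seq_len(n), function(i)
    oracle_aj(time[-i], event[-i], t), numeric(1))
  n * full - (n - 1) * loo
}

# exhaustive pair enumeration of concordance between theta and risk
oracle_concordance <- function(theta, risk) {
  conc <- 0; disc <- 0; tied <- 0
  n <- length(theta)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (theta[i] == theta[j]) next
    hi <- if (theta[i] > theta[j]) i else j
    lo <- if (theta[i] > theta[j]) j else i
    if (risk[hi] > risk[lo]) conc <- conc + 1
    else if (risk[hi] < risk[lo]) disc <- disc + 1
    else tied <- tied + 1
  }
  (conc + tied / 2) / (conc + disc + tied)
}

# restricted log-likelihood of the random-effects model
oracle_reml_ll <- function(tau2, y, s) {
  v <- s^2 + tau2
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  -0.5 * sum(log(v)) - 0.5 * log(sum(w)) - 0.5 * sum(w * (y - mu)^2)
}

# grid + golden-section refinement of the REML tau^2
oracle_reml_tau2 <- function(y, s, upper = NULL) {
  if (is.null(upper)) upper <- max(1e-8, 10 * stats::var(y))
  grid <- seq(0, upper, length.out = 2000)
  ll <- vapply(grid, oracle_reml_ll, numeric(1), y = y, s = s)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(oracle_reml_ll, c(lo, hi), y = y, s = s,
                         maximum = TRUE, tol = 1e-12)
  if (oracle_reml_ll(0, y, s) >= opt$objective) 0 else opt$maximum
}

# hand product-limit Kaplan-Meier of the censoring distribution
oracle_censor_km <- function(time, event, t) {
  ut <- sort(unique(time))
  g <- 1
  for (s in ut) {
    if (s > t) break
    n_risk <- sum(time >= s)
    d_c <- sum(time == s & event == 0)
    g <- g * (1 - d_c / n_risk)
  }
  g
}

# small random competing-risks instance (ties possible when gridded)
random_outcomes <- function(n, gridded = FALSE) {
  tm <- if (gridded) sample(1:8, n, replace = TRUE) / 2 else
    round(stats::rexp(n, 0.3) + 0.01, 3)
  data.frame(patient_id = seq_len(n), time = tm,
             event = sample(0:2, n, replace = TRUE,
                            prob = c(0.3, 0.4, 0.3)))
}

# draw cause-1/cause-2 outcomes from the generator's subdistribution
# family for an arbitrary linear predictor vector (used by FP and
# calibration tests, independent of generate_cohort's covariate model)
sim_subdist_outcomes <- function(lp, p = 0.4, cause2_rate = 0.02,
                                 censor_rate = 0, horizon = 10) {
  n <- length(lp)
  eta <- exp(lp)
  mass1 <- 1 - (1 - p)^eta
  cause1 <- stats::runif(n) < mass1
  u <- stats::runif(n)
  tt <- numeric(n)
  i1 <- which(cause1)
  inner <- (1 - u[i1] * mass1[i1])^(1 / eta[i1])
  tt[i1] <- -log(1 - (1 - inner) / p)
  tt[!cause1] <- stats::rexp(sum(!cause1), cause2_rate)
  ev <- ifelse(cause1, 1L, 2L)
  cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  obs <- pmin(tt, cens, horizon)
  ev[obs < tt] <- 0L
  data.frame(patient_id = seq_len(n), time = pmax(obs, 1e-8), event = ev)
}

# compact complete patient table for fast Fine-Gray fits in tests
small_patients <- function(n) {
  data.frame(patient_id = seq_len(n),
             practice_id = sample(1:4, n, replace = TRUE),
             age = stats::runif(n, 40, 90),
             sex = sample(c("female", "male"), n, replace = TRUE),
             cholesterol = stats::rnorm(n, 5.3, 1.1),
             previous_falls = stats::rbinom(n, 1, 0.3),
             stringsAsFactors = FALSE)
}

small_predictors <- c("age", "sex", "cholesterol", "previous_falls")
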