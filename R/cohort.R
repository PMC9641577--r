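#' Simulation configuration for a synthetic primary-care cohort
#'
#' Defines the conditions under which [generate_cohort()] simulates a
#' clustered primary-care cohort with a Fine-Gray event process for serious
#' falls (cause 1) and death from other causes (cause 2).
#'
#' The cause-1 event process follows the subdistribution
#' \deqn{F_1(t \mid x) = 1 - \{1 - p(1 - e^{-t})\}^{\exp(x\beta)},}
#' so that the true model is exactly a Fine-Gray subdistribution hazard model
#' with log-SHR vector `beta_true`. The overall cause-1 mass `p` and the
#' cause-2 exponential rate are, by default, tuned numerically so that the
#' population 10-year cumulative incidences match `target_cif1` and
#' `target_cif2` given the realised covariate distribution.
#'
#' @param n_patients number of patients.
#' @param n_practices number of general practices (clusters); practice sizes
#'   are drawn from a log-normal distribution with log-scale standard
#'   deviation `practice_size_sdlog`.
#' @param practice_size_sdlog dispersion of practice sizes.
#' @param practice_sd standard deviation of the practice-level random
#'   intercept added to the linear predictor of the subdistribution hazard.
#' @param beta_true named vector of true log subdistribution hazard ratios;
#'   names must match columns of [design_matrix()]. Defaults to the bundled
#'   [default_beta_true()].
#' @param p overall cause-1 mass in (0,1), or `NA` to tune it to
#'   `target_cif1` at 10 years.
#' @param cause2_rate exponential rate for cause-2 event times, or `NA` to
#'   tune it to `target_cif2` at 10 years.
#' @param target_cif1,target_cif2 10-year cumulative incidence targets for
#'   falls and competing death used when `p`/`cause2_rate` are `NA`.
#' @param censor_rate rate of the exponential dropout process (0 = none).
#' @param entry_window width in years of the staggered cohort-entry window:
#'   each patient's administrative censoring time is the smaller of the
#'   horizon and a uniform draw over (0, entry_window), emulating a fixed
#'   study end date with entry spread over the study period (0 = everyone
#'   observed to the horizon).
#' @param horizon administrative censoring time in years.
#' @param miss_rates named vector of missingness rates in `[0,1)` for the
#'   imputable variables (cholesterol, ethnicity, imd_quintile, smoking,
#'   alcohol).
#' @param seed integer seed; all randomness in [generate_cohort()] is routed
#'   through it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 10000,
                       n_practices = 50,
                       practice_size_sdlog = 0.7,
                       practice_sd = 0.18,
                       beta_true = default_beta_true(),
                       p = NA_real_,
                       cause2_rate = NA_real_,
                       target_cif1 = 0.035,
                       target_cif2 = 0.103,
                       censor_rate = 0.03,
                       entry_window = 21,
                       horizon = 10,
                       miss_rates = c(cholesterol = 0.489, ethnicity = 0.56,
                                      imd_quintile = 0, smoking = 0.05,
                                      alcohol = 0.15),
                       seed = 1L) {
  if (n_patients < 1 || n_practices < 1)
    stop("n_patients and n_practices must be positive")
  if (!is.na(p) && (p <= 0 || p >= 1))
    stop("cause-1 mass p must lie in (0, 1)")
  if (any(miss_rates < 0) || any(miss_rates >= 1))
    stop("missingness rates must lie in [0, 1)")
  if (horizon <= 0) stop("horizon must be positive")
  allowed <- c("cholesterol", "ethnicity", "imd_quintile", "smoking", "alcohol")
  if (is.null(names(miss_rates)) || !all(names(miss_rates) %in% allowed))
    stop("miss_rates must be named and restricted to: ",
         paste(allowed, collapse = ", "))
  structure(list(n_patients = as.integer(n_patients),
                 n_practices = as.integer(n_practices),
                 practice_size_sdlog = practice_size_sdlog,
                 practice_sd = practice_sd,
                 beta_true = beta_true,
                 p = p, cause2_rate = cause2_rate,
                 target_cif1 = target_cif1, target_cif2 = target_cif2,
                 censor_rate = censor_rate, entry_window = entry_window,
                 horizon = horizon,
                 miss_rates = miss_rates, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default true log subdistribution hazard ratios
#'
#' Per-unit effects on the subdistribution hazard of a serious fall used by
#' the generator: roughly a 6% hazard increase per five years of age, a 25%
#' increase for women, effects per mmol/L cholesterol and per unit frailty
#' index, and binary-flag effects typical of adjusted falls models in primary
#' care (history of falls, multiple sclerosis and heavy drinking strongest).
#'
#' @return Named numeric vector keyed by [design_matrix()] columns.
#' @export
default_beta_true <- function() {
  c(age = log(1.06) / 5, sexfemale = log(1.25), cholesterol = log(1.48),
    frailty_index = log(1.22) / (4 / 36),
    ethnicityblack = log(0.65), ethnicitysouth_asian = log(0.68),
    ethnicityother = log(0.70),
    imd2 = log(1.04), imd3 = log(1.07), imd4 = log(1.18), imd5 = log(1.35),
    smokingformer = log(1.12), smokingcurrent = log(1.27),
    alcoholoccasional = log(0.90), alcohollight = log(0.94),
    alcoholmoderate = log(0.99), alcoholheavy = log(1.57),
    alcoholunknown_amount = log(0.93),
    previous_falls = log(1.32), memory_problems = log(1.17),
    mobility_problems = log(0.92), stroke = log(1.14),
    multiple_sclerosis = log(1.71),
    acei = log(1.12), arb = log(1.19), alpha_blocker = log(1.04),
    beta_blocker = log(1.07), ccb = log(1.08), diuretic = log(1.07),
    other_antihypertensive = log(0.96),
    opioid = log(1.11), hypnotic_anxiolytic = log(1.15),
    antidepressant = log(1.16), anticholinergic = log(1.03))
}

# reference covariate values at which the true linear predictor is zero
truth_center <- function() {
  c(age = 60, cholesterol = 5.3, frailty_index = 1 / 36)
}

#' Closed-form cause-1 subdistribution cumulative incidence
#'
#' Evaluates \eqn{F_1(t \mid x) = 1 - \{1 - p(1-e^{-t})\}^{\exp(lp)}}, the
#' cumulative incidence function of the generator's cause-1 event process.
#'
#' @param t time in years (vectorised).
#' @param lp linear predictor \eqn{x\beta} (vectorised).
#' @param p overall cause-1 mass in (0,1).
#' @return Cumulative incidence values in `[0,1)`.
#' @export
subdistribution_cif <- function(t, lp, p) {
  stopifnot(p > 0, p < 1)
  1 - (1 - p * (1 - exp(-t)))^exp(lp)
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

# solve the intercept of a logistic model so the marginal mean equals target
solve_logit_intercept <- function(target, offset) {
  f <- function(a) mean(stats::plogis(a + offset)) - target
  stats::uniroot(f, c(-25, 25), tol = 1e-10)$root
}

#' Generate a synthetic clustered primary-care cohort
#'
#' Simulates patients nested in general practices with predictor marginals
#' matching a large English primary-care population indicated for
#' antihypertensive treatment (mean age about 59 (SD 13), 52% women, systolic
#' blood pressure confined to 130-179 mm Hg, low median frailty), and draws
#' competing-risks outcomes from a Fine-Gray-consistent event process with
#' known true parameters (see [sim_config()]). Age drives frailty,
#' comorbidity flags and prescription flags through logistic models, giving a
#' realistic positive dependence among predictors.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `cohort_sim` with elements
#'   \describe{
#'     \item{patients}{data frame, one row per patient: identifiers,
#'       demographics, clinical measurements and binary flags.}
#'     \item{outcomes}{data frame with `patient_id`, `time` (years from the
#'       index date) and `event` (0 censored, 1 fall, 2 competing death).}
#'     \item{truth}{list with the tuned `p`, `cause2_rate`, per-patient true
#'       linear predictor `lp` (including the practice effect) and the
#'       practice random effects.}
#'     \item{config}{the configuration, with tuned parameters filled in.}
#'   }
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_patients

  # practices: log-normal sizes normalised to n
  w <- stats::rlnorm(config$n_practices, sdlog = config$practice_size_sdlog)
  practice_id <- sample(rep.int(seq_len(config$n_practices),
                                times = pmax(1L, round(w / sum(w) * n))),
                        n, replace = TRUE)
  u <- stats::rnorm(config$n_practices, 0, config$practice_sd)

  age <- rtrunc_norm(n, 59.4, 13.2, lower = 40)
  za <- (age - 60) / 10
  sex <- ifelse(stats::runif(n) < 0.52, "female", "male")
  ethnicity <- sample(c("white", "black", "south_asian", "other"), n,
                      replace = TRUE, prob = c(0.947, 0.014, 0.019, 0.020))
  imd_quintile <- sample(1:5, n, replace = TRUE,
                         prob = c(0.237, 0.229, 0.213, 0.177, 0.144))
  smoking <- sample(c("non", "former", "current"), n, replace = TRUE,
                    prob = c(0.504, 0.280, 0.216))
  alcohol <- sample(c("non", "occasional", "light", "moderate", "heavy",
                      "unknown_amount"), n, replace = TRUE,
                    prob = c(0.192, 0.323, 0.159, 0.118, 0.015, 0.193))
  cholesterol <- 4.6 + 0.012 * age + stats::rnorm(n, 0, 1.05)
  # frailty: accumulated deficits out of 36, prevalence rising with age
  frailty_index <- stats::rbinom(n, 36, stats::plogis(-3.4 + 0.5 * za)) / 36
  sbp <- rtrunc_norm(n, 143.5, 11.9, lower = 130, upper = 179)
  dbp <- stats::rnorm(n, 83.8, 9.6)

  flags <- c(previous_falls = 0.06, memory_problems = 0.016,
             mobility_problems = 0.012, stroke = 0.025,
             multiple_sclerosis = 0.004, acei = 0.12, arb = 0.03,
             alpha_blocker = 0.02, beta_blocker = 0.12, ccb = 0.11,
             diuretic = 0.10, other_antihypertensive = 0.006, opioid = 0.31,
             hypnotic_anxiolytic = 0.21, antidepressant = 0.21,
             anticholinergic = 0.11)
  age_slope <- c(multiple_sclerosis = 0, antidepressant = 0.1,
                 opioid = 0.15, hypnotic_anxiolytic = 0.2)
  pat <- data.frame(patient_id = seq_len(n), practice_id = practice_id,
                    age = age, sex = sex, ethnicity = ethnicity,
                    imd_quintile = imd_quintile, smoking = smoking,
                    alcohol = alcohol, cholesterol = cholesterol,
                    frailty_index = frailty_index, sbp = sbp, dbp = dbp,
                    stringsAsFactors = FALSE)
  for (v in names(flags)) {
    b <- if (v %in% names(age_slope)) age_slope[[v]] else 0.35
    a <- solve_logit_intercept(flags[[v]], b * za)
    pat[[v]] <- as.integer(stats::runif(n) < stats::plogis(a + b * za))
  }

  # true linear predictor (centered at the truth reference values)
  X <- design_matrix(pat)
  bt <- config$beta_true
  miss <- setdiff(names(bt), colnames(X))
  if (length(miss)) stop("beta_true names not in design: ",
                         paste(miss, collapse = ", "))
  ctr <- truth_center()
  Xc <- X[, names(bt), drop = FALSE]
  for (v in intersect(names(ctr), colnames(Xc))) Xc[, v] <- Xc[, v] - ctr[[v]]
  lp <- drop(Xc %*% bt) + u[practice_id]
  eta <- exp(lp)

  # tune p and the cause-2 rate to the 10-year cumulative incidence targets
  k10 <- 1 - exp(-10)
  p <- config$p
  if (is.na(p)) {
    f <- function(q) mean(1 - (1 - q * k10)^eta) - config$target_cif1
    p <- stats::uniroot(f, c(1e-8, 0.999), tol = 1e-12)$root
  }
  mass2 <- mean((1 - p)^eta)
  rate2 <- config$cause2_rate
  if (is.na(rate2)) {
    if (config$target_cif2 >= mass2)
      stop("target_cif2 unattainable given cause-1 mass")
    rate2 <- -log(1 - config$target_cif2 / mass2) / 10
  }

  # indirect simulation: draw the cause, then the conditional event time
  cause1 <- stats::runif(n) < (1 - (1 - p)^eta)
  tt <- numeric(n)
  uu <- stats::runif(n)
  i1 <- which(cause1)
  if (length(i1)) {
    e1 <- eta[i1]
    mass1 <- 1 - (1 - p)^e1
    inner <- (1 - uu[i1] * mass1)^(1 / e1)
    tt[i1] <- -log(1 - (1 - inner) / p)
  }
  i2 <- which(!cause1)
  tt[i2] <- stats::qexp(uu[i2], rate = rate2)
  event <- ifelse(cause1, 1L, 2L)

  cens <- if (config$censor_rate > 0)
    stats::rexp(n, config$censor_rate) else rep(Inf, n)
  if (config$entry_window > 0)
    cens <- pmin(cens, stats::runif(n, 0, config$entry_window))
  obs <- pmin(tt, cens, config$horizon)
  event[obs < tt] <- 0L
  obs <- pmax(obs, 1e-8)

  out_config <- config
  out_config$p <- p
  out_config$cause2_rate <- rate2
  structure(list(patients = pat,
                 outcomes = data.frame(patient_id = pat$patient_id,
                                       time = obs, event = event),
                 truth = list(p = p, cause2_rate = rate2, lp = lp,
                              practice_effects = u,
                              beta_true = bt),
                 config = out_config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  tab <- table(factor(x$outcomes$event, levels = 0:2))
  cat("Synthetic competing-risks cohort\n")
  cat(sprintf("  %d patients in %d practices; seed %d\n",
              nrow(x$patients), x$config$n_practices, x$config$seed))
  cat(sprintf("  events: %d falls, %d competing deaths, %d censored\n",
              tab[["1"]], tab[["2"]], tab[["0"]]))
  cat(sprintf("  cause-1 mass p = %.4f, cause-2 rate = %.4f\n",
              x$truth$p, x$truth$cause2_rate))
  invisible(x)
}

#' Blood-pressure eligibility filter
#'
#' Applies the cohort eligibility rules: patients aged 40 or older, with at
#' least one systolic reading in 130-179 mm Hg and no reading above
#' 180 mm Hg. Cohort entry is the date of the first qualifying reading and
#' the index date (the prediction time origin) is 12 months later.
#'
#' @param bp data frame with columns `patient_id`, `date` (numeric years or
#'   `Date`) and `sbp` (mm Hg).
#' @param ages named vector (or data frame with `patient_id`, `age`) of ages
#'   in years at first reading.
#' @return Data frame with one row per included patient: `patient_id`,
#'   `entry_date`, `index_date`. Patients with no readings are excluded with
#'   a warning.
#' @export
apply_eligibility <- function(bp, ages) {
  if (is.data.frame(ages)) {
    a <- ages$age
    names(a) <- as.character(ages$patient_id)
    ages <- a
  }
  if (nrow(bp) == 0) stop("empty blood-pressure series")
  if (any(bp$sbp <= 0)) stop("systolic readings must be positive")
  ids <- unique(as.character(bp$patient_id))
  no_read <- setdiff(names(ages), ids)
  if (length(no_read))
    warning("excluded (no readings): ", paste(no_read, collapse = ", "))
  res <- lapply(ids, function(id) {
    s <- bp[as.character(bp$patient_id) == id, , drop = FALSE]
    s <- s[order(s$date), , drop = FALSE]
    if (is.na(ages[id]) || ages[id] < 40) return(NULL)
    if (any(s$sbp > 180)) return(NULL)
    ok <- which(s$sbp >= 130 & s$sbp <= 179)
    if (!length(ok)) return(NULL)
    entry <- s$date[ok[1]]
    index <- if (inherits(entry, "Date")) entry + 365 else entry + 1
    data.frame(patient_id = id, entry_date = entry, index_date = index,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Impose missing-at-random missingness on the imputable variables
#'
#' Sets values to `NA` in the five variables the analysis imputes
#' (cholesterol, ethnicity, deprivation quintile, smoking, alcohol), with a
#' missingness probability depending on observed age and sex only (MAR).
#' Binary diagnosis/prescription flags are never set missing: absence of a
#' code is taken to mean absence of the condition.
#'
#' @param patients patient data frame from [generate_cohort()].
#' @param rates named vector of marginal missingness rates in `[0,1)`.
#' @param mar_strength log-odds shift per decade of age (and half that for
#'   female sex) in the missingness model; 0 gives MCAR.
#' @param seed integer seed.
#' @return The patient data frame with `NA`s inserted.
#' @export
impose_missingness <- function(patients,
                               rates = c(cholesterol = 0.489,
                                         ethnicity = 0.56,
                                         imd_quintile = 0,
                                         smoking = 0.05, alcohol = 0.15),
                               mar_strength = 0.3, seed = 1L) {
  allowed <- c("cholesterol", "ethnicity", "imd_quintile", "smoking", "alcohol")
  if (is.null(names(rates)) || !all(names(rates) %in% allowed))
    stop("rates must be named and restricted to: ",
         paste(allowed, collapse = ", "))
  if (any(rates >= 1) || any(rates < 0)) stop("rates must lie in [0, 1)")
  set.seed(seed)
  off <- mar_strength * (patients$age - 60) / 10 +
    (mar_strength / 2) * (patients$sex == "female")
  for (v in names(rates)) {
    r <- rates[[v]]
    if (r == 0) next
    a <- solve_logit_intercept(r, off)
    hit <- stats::runif(nrow(patients)) < stats::plogis(a + off)
    patients[[v]][hit] <- NA
  }
  patients
}
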