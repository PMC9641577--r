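#' Nelson-Aalen outcome covariates for imputation models
#'
#' Computes the Nelson-Aalen estimates of the cumulative cause-specific
#' hazards for falls (\eqn{H_1}) and competing death (\eqn{H_2}),
#' \eqn{H_k(t) = \sum_{t_j \le t} d_{kj}/n_j}, evaluated at each patient's
#' own follow-up time, together with the binary event indicators. These
#' enter the chained-equation imputation models so the imputations condition
#' on the competing-risks outcome.
#'
#' @param outcomes data frame with `patient_id`, `time`, `event`.
#' @return Data frame with `patient_id`, `na_fall`, `na_death`, `d_fall`,
#'   `d_death`.
#' @export
nelson_aalen_covariates <- function(outcomes) {
  check_outcomes(outcomes)
  cnt <- event_counts(outcomes$time, outcomes$event)
  h1 <- cumsum(cnt$d1 / cnt$n)
  h2 <- cumsum(cnt$d2 / cnt$n)
  j <- findInterval(outcomes$time, cnt$ut)
  data.frame(patient_id = outcomes$patient_id,
             na_fall = ifelse(j == 0, 0, h1[pmax(j, 1)]),
             na_death = ifelse(j == 0, 0, h2[pmax(j, 1)]),
             d_fall = as.integer(outcomes$event == 1),
             d_death = as.integer(outcomes$event == 2))
}

imputable_vars <- c("cholesterol", "ethnicity", "imd_quintile", "smoking",
                    "alcohol")

# design frame used by the chained imputation models: current (filled)
# values of every model covariate except `target`, plus the outcome
# covariates
imp_design <- function(dat, target, predictors, na_cov) {
  keep <- setdiff(intersect(predictors, names(dat)), target)
  df <- dat[, keep, drop = FALSE]
  for (v in intersect(names(cat_levels), names(df)))
    df[[v]] <- factor(df[[v]], levels = cat_levels[[v]])
  if ("imd_quintile" %in% names(df))
    df$imd_quintile <- factor(df$imd_quintile, levels = 1:5)
  if ("sex" %in% names(df)) df$sex <- factor(df$sex,
                                             levels = c("male", "female"))
  df <- cbind(df, na_cov[, c("na_fall", "na_death", "d_fall", "d_death")])
  stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
}

draw_norm <- function(y, X, Xmis) {
  fit <- stats::lm.fit(cbind(1, X), y)
  qr_ <- fit$qr
  df <- length(y) - fit$rank
  sigma2 <- sum(fit$residuals^2) / stats::rchisq(1, df)
  R <- qr.R(qr_)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pert <- backsolve(R, stats::rnorm(fit$rank)) * sqrt(sigma2)
  bstar <- beta
  bstar[seq_len(fit$rank)] <- beta[seq_len(fit$rank)] + pert
  mu <- drop(cbind(1, Xmis) %*% bstar)
  list(mean = mu, sd = sqrt(sigma2),
       fitted_obs = drop(cbind(1, X) %*% bstar))
}

impute_continuous <- function(y, X, mis, method) {
  d <- draw_norm(y[!mis], X[!mis, , drop = FALSE], X[mis, , drop = FALSE])
  if (method == "pmm") {
    obs_val <- y[!mis]
    k <- 5L
    vapply(d$mean, function(m) {
      nb <- order(abs(d$fitted_obs - m))[seq_len(min(k, length(obs_val)))]
      obs_val[sample(nb, 1)]
    }, numeric(1))
  } else {
    d$mean + stats::rnorm(sum(mis), 0, d$sd)
  }
}

impute_categorical <- function(y, X, mis) {
  yf <- factor(y[!mis])
  boot <- sample(length(yf), replace = TRUE)  # parameter uncertainty
  fit <- nnet::multinom(yf[boot] ~ ., data = data.frame(X[!mis, , drop =
                          FALSE])[boot, , drop = FALSE],
                        trace = FALSE, maxit = 200)
  pr <- stats::predict(fit, newdata = data.frame(X[mis, , drop = FALSE]),
                       type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # binary case
  lev <- levels(yf)
  apply(pr, 1, function(p) sample(lev, 1, prob = p))
}

#' Multiple imputation by chained equations
#'
#' Imputes missing values in the five imputable predictors (cholesterol,
#' ethnicity, deprivation quintile, smoking, alcohol) by chained equations:
#' stochastic Bayesian linear regression for continuous variables
#' (optionally predictive-mean matching, which avoids implausible negative
#' cholesterol draws) and bootstrap multinomial logistic regression for
#' categorical variables. Every imputation model conditions on all other
#' model covariates plus the Nelson-Aalen cumulative-hazard covariates and
#' the event indicators from [nelson_aalen_covariates()].
#'
#' @param patients patient data frame, possibly with `NA`s in the imputable
#'   variables.
#' @param outcomes fully observed outcome data frame.
#' @param m number of imputed copies (default 10).
#' @param cycles chained-equation cycles per copy (default 10).
#' @param predictors model covariates used in the imputation models.
#' @param method named character vector overriding the per-variable method;
#'   continuous variables accept `"norm"` (default) or `"pmm"`.
#' @param seed integer seed.
#' @return An object of class `imputed_stack`: list with `m`, `copies` (m
#'   complete patient tables agreeing on all observed cells), `methods`,
#'   `trace` (per-cycle means of imputed continuous values, for convergence
#'   monitoring) and `seed`.
#' @export
mice_impute <- function(patients, outcomes, m = 10, cycles = 10,
                        predictors = default_predictors(),
                        method = NULL, seed = 1L) {
  check_outcomes(outcomes)
  o <- outcomes[match(patients$patient_id, outcomes$patient_id), ]
  na_cov <- nelson_aalen_covariates(o)
  vars <- intersect(imputable_vars, names(patients))
  vars <- vars[vapply(vars, function(v) anyNA(patients[[v]]), logical(1))]
  all_na <- vars[vapply(vars, function(v) all(is.na(patients[[v]])),
                        logical(1))]
  if (length(all_na))
    stop("variable(s) 100% missing: ", paste(all_na, collapse = ", "))
  bad <- setdiff(names(which(vapply(patients, anyNA, logical(1)))),
                 imputable_vars)
  if (length(bad))
    stop("missingness outside the imputable variables: ",
         paste(bad, collapse = ", "))
  methods <- vapply(vars, function(v)
    if (v == "cholesterol") "norm" else "polyreg", character(1))
  if (!is.null(method)) methods[names(method)] <- method

  set.seed(seed)
  if (!length(vars)) {
    return(structure(list(m = m, copies = replicate(m, patients,
                                                    simplify = FALSE),
                          methods = methods, trace = NULL, seed = seed),
                     class = "imputed_stack"))
  }
  mis_idx <- lapply(vars, function(v) is.na(patients[[v]]))
  names(mis_idx) <- vars
  copies <- vector("list", m)
  trace <- array(NA_real_, dim = c(m, cycles, length(vars)),
                 dimnames = list(NULL, NULL, vars))
  for (im in seq_len(m)) {
    dat <- patients
    for (v in vars) {  # starting fill: random draws from observed values
      obs <- dat[[v]][!mis_idx[[v]]]
      dat[[v]][mis_idx[[v]]] <- sample(obs, sum(mis_idx[[v]]),
                                       replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (v in vars) {
        mis <- mis_idx[[v]]
        X <- imp_design(dat, v, predictors, na_cov)
        if (methods[[v]] %in% c("norm", "pmm")) {
          dat[[v]][mis] <- impute_continuous(dat[[v]], X, mis, methods[[v]])
          trace[im, cy, v] <- mean(dat[[v]][mis])
        } else {
          val <- impute_categorical(dat[[v]], X, mis)
          if (v == "imd_quintile") val <- as.integer(val)
          dat[[v]][mis] <- val
          trace[im, cy, v] <- mean(dat[[v]][mis] ==
                                     dat[[v]][mis][1])  # share of modal draw
        }
      }
    }
    copies[[im]] <- dat
  }
  structure(list(m = m, copies = copies, methods = methods, trace = trace,
                 seed = seed),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("Imputed stack: m = %d copies (seed %d)\n", x$m, x$seed))
  if (length(x$methods))
    cat("  methods:", paste(names(x$methods), x$methods, sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates numeric vector of per-imputation estimates.
#' @param variances numeric vector of per-imputation squared standard
#'   errors.
#' @return An object of class `pooled_estimate`: `estimate` (mean), `W`
#'   (within-imputation variance), `B` (between-imputation variance),
#'   `T = W + (1 + 1/m) B` (total variance) and the classical degrees of
#'   freedom \eqn{(m-1)(1 + W/((1+1/m)B))^2}.
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) stop("Rubin's rules require m >= 2")
  if (length(variances) != m) stop("estimates and variances must align")
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  df <- if (B == 0) Inf else (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
  structure(list(estimate = mean(estimates), W = W, B = B, T = Tv, df = df,
                 m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate %.4f (SE %.4f; W %.4g, B %.4g, df %.1f, m %d)\n",
    x$estimate, sqrt(x$T), x$W, x$B, x$df, x$m))
  invisible(x)
}

#' Median/IQR summary across imputations
#'
#' Used when Rubin's rules do not apply (non-normal posterior, e.g. the
#' explained-variation statistic).
#'
#' @param values numeric vector of per-imputation values.
#' @return List with `median`, `iqr`, and the quartiles `q1`, `q3`.
#' @export
median_iqr_pool <- function(values) {
  if (!length(values)) stop("no values supplied")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], iqr = q[3] - q[1], q1 = q[1], q3 = q[3])
}
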