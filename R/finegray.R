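#' Kaplan-Meier estimate of the censoring distribution
#'
#' Estimates the survival function \eqn{\hat G(t)} of the censoring process
#' by Kaplan-Meier with the censoring indicator as the event. \eqn{\hat G}
#' enters the Fine-Gray weighting scheme as
#' \eqn{w_i(t) = \hat G(t)/\hat G(\min(T_i, t))}, which keeps patients with a
#' competing death in later risk sets with decaying weight.
#'
#' @param outcomes data frame with `time` and `event` (0/1/2).
#' @return A right-continuous step function `G(t)` with `G(0) = 1`.
#' @export
censoring_km <- function(outcomes) {
  check_outcomes(outcomes)
  fit <- survival::survfit(survival::Surv(outcomes$time,
                                          outcomes$event == 0) ~ 1)
  stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
}

check_outcomes <- function(outcomes) {
  stopifnot(all(c("time", "event") %in% names(outcomes)))
  if (any(outcomes$time <= 0)) stop("follow-up times must be positive")
  if (!all(outcomes$event %in% 0:2)) stop("event codes must be 0, 1 or 2")
  invisible(outcomes)
}

#' Fit a Fine-Gray subdistribution hazard model
#'
#' Estimates the log subdistribution hazard ratios for serious falls
#' (cause 1) under the competing risk of death from other causes (cause 2),
#' by maximising the inverse-probability-of-censoring-weighted partial
#' likelihood in which patients with a competing event remain in later risk
#' sets with weight \eqn{\hat G(t)/\hat G(T_i)}. Fitting proceeds through
#' the weighted risk-set expansion of `survival::finegray()` and a weighted
#' Cox partial likelihood with Breslow tie handling; standard errors are
#' robust (infinitesimal jackknife, clustered on patient). The baseline
#' cumulative subdistribution hazard \eqn{H_0(t)} is the Breslow-type
#' estimator evaluated at the covariate centering values (the training
#' means), and the baseline cumulative incidence is
#' \eqn{CIF_0(t) = 1 - \exp\{-H_0(t)\}}.
#'
#' @param patients complete (no missing predictors) patient data frame.
#' @param outcomes outcome data frame aligned with `patients` by
#'   `patient_id`.
#' @param transforms optional named list of [fp_transform()] objects for
#'   continuous predictors.
#' @param predictors predictor set; defaults to the 24-predictor falls model.
#' @param exclude optional character vector of predictors to drop (explicit
#'   user-controlled pruning; no automated selection is performed).
#' @param keep_fit keep the underlying weighted Cox fit (needed by
#'   [schoenfeld_check()]).
#' @return An object of class `fg_model` with elements `coefficients`, `se`,
#'   `vcov`, `transforms`, `center` (centering constants on the transformed
#'   scale), `baseline` (data frame `time`, `hazard`, `cif0`), `n`,
#'   `n_events` and convergence metadata.
#' @export
fit_finegray <- function(patients, outcomes, transforms = NULL,
                         predictors = default_predictors(),
                         exclude = NULL, keep_fit = TRUE) {
  check_outcomes(outcomes)
  predictors <- setdiff(predictors, exclude)
  o <- outcomes[match(patients$patient_id, outcomes$patient_id), ]
  if (anyNA(o$time)) stop("every patient needs exactly one outcome record")
  X <- design_matrix(patients, transforms, predictors)
  if (anyNA(X)) stop("missing covariate values; impute before fitting")
  if (sum(o$event == 1) < 1) stop("at least one cause-1 event is required")

  dat <- data.frame(X, check.names = FALSE)
  dat$.time <- o$time
  dat$.status <- factor(o$event, levels = 0:2,
                        labels = c("censor", "fall", "death"))
  dat$.id <- patients$patient_id
  fg <- survival::finegray(survival::Surv(.time, .status) ~ ., data = dat,
                           etype = "fall", id = .id)
  xn <- colnames(X)
  f <- stats::as.formula(paste(
    "survival::Surv(fgstart, fgstop, fgstatus) ~",
    paste(sprintf("`%s`", xn), collapse = " + ")))
  fit <- survival::coxph(f, data = fg, weights = fg$fgwt, ties = "breslow",
                         robust = TRUE, cluster = .id, x = TRUE)
  beta <- stats::coef(fit)
  names(beta) <- xn
  if (anyNA(beta))
    stop("collinear covariates: ", paste(xn[is.na(beta)], collapse = ", "))
  if (any(!is.finite(beta)))
    stop("Fine-Gray fit did not converge (non-finite coefficients): ",
         paste(xn[!is.finite(beta)], collapse = ", "))

  center <- colMeans(X)
  bh <- survival::basehaz(fit, centered = FALSE)
  H0 <- bh$hazard * exp(sum(center * beta))
  se <- sqrt(diag(fit$var))
  names(se) <- xn
  V <- fit$var
  dimnames(V) <- list(xn, xn)
  structure(list(coefficients = beta, se = se, vcov = V,
                 transforms = transforms, center = center,
                 baseline = data.frame(time = bh$time, hazard = H0,
                                       cif0 = 1 - exp(-H0)),
                 predictors = predictors, n = nrow(patients),
                 n_events = sum(o$event == 1),
                 loglik = fit$loglik[2], iter = fit$iter,
                 fit = if (keep_fit) fit else NULL),
            class = "fg_model")
}

#' @export
print.fg_model <- function(x, ...) {
  cat(sprintf(
    "Fine-Gray subdistribution hazard model: %d patients, %d falls\n",
    x$n, x$n_events))
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                    se = x$se, z = x$coefficients / x$se,
                    check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("Baseline CIF at last event time: %.4f\n",
              max(x$baseline$cif0)))
  invisible(x)
}

baseline_cif_at <- function(model, t) {
  if (any(t < 0)) stop("t must be non-negative")
  b <- model$baseline
  f <- stats::stepfun(b$time, c(0, b$cif0))
  f(t)
}

#' Linear predictor of a fitted Fine-Gray model
#'
#' @param model an `fg_model` (or serialized equivalent).
#' @param patients patient data frame with the model's predictors.
#' @return Numeric vector of centered linear predictors
#'   \eqn{(x - \bar x)\beta}.
#' @export
linear_predictor <- function(model, patients) {
  X <- design_matrix(patients, model$transforms, model$predictors)
  miss <- setdiff(names(model$coefficients), colnames(X))
  if (length(miss)) stop("missing design columns: ",
                         paste(miss, collapse = ", "))
  X <- X[, names(model$coefficients), drop = FALSE]
  drop(sweep(X, 2, model$center) %*% model$coefficients)
}

#' Predicted cumulative incidence of a fall
#'
#' Evaluates \eqn{F_1(t \mid x) = 1 - \{1 - CIF_0(t)\}^{\exp(LP)}} with
#' centered linear predictor \eqn{LP}.
#'
#' @param model an `fg_model`.
#' @param patients patient data frame, or `NULL` to use `lp`.
#' @param t horizon(s) in years.
#' @param lp optionally, precomputed linear predictors.
#' @return If one horizon: numeric vector of risks; else a matrix with one
#'   column per horizon.
#' @export
predict_cif <- function(model, patients = NULL, t = 10, lp = NULL) {
  if (any(t < 0)) stop("t must be non-negative")
  if (is.null(lp)) lp <- linear_predictor(model, patients)
  cif0 <- baseline_cif_at(model, t)
  out <- sapply(cif0, function(c0) 1 - (1 - c0)^exp(lp))
  out <- matrix(out, nrow = length(lp),
                dimnames = list(NULL, paste0("t", t)))
  if (length(t) == 1) unname(drop(out)) else out
}

fp_shift_for <- function(x) {
  m <- min(x, na.rm = TRUE)
  if (m > 0) 0 else -m + 1
}

fit_deviance <- function(patients, outcomes, transforms, predictors) {
  m <- fit_finegray(patients, outcomes, transforms, predictors,
                    keep_fit = FALSE)
  -2 * m$loglik
}

#' Select a fractional polynomial transform for a continuous predictor
#'
#' Searches the 8 FP1 powers and 36 FP2 power pairs for the best-fitting
#' functional form of `variable` in the Fine-Gray model (all other
#' predictors entering linearly), comparing fitted deviances. Lower-order
#' forms are preferred wherever possible: the best FP2 must improve on the
#' best FP1 by the 0.95 chi-squared quantile on 2 degrees of freedom, and
#' the best FP1 must improve on the linear form by the 0.95 quantile on 1
#' degree of freedom, otherwise the simpler form is kept.
#'
#' When `patients` is an [mice_impute()] stack, the search runs separately
#' in each imputed copy and the most frequent winner is selected, with ties
#' broken toward lower order and then toward the linear transform.
#'
#' @param patients complete patient data frame, or an `imputed_stack`.
#' @param outcomes outcome data frame.
#' @param variable name of the continuous predictor.
#' @param predictors predictor set for the adjusting model.
#' @param max_degree 1 restricts the search to FP1; 2 (default) allows FP2.
#' @return The selected [fp_transform()].
#' @export
select_fractional_polynomial <- function(patients, outcomes, variable,
                                         predictors = default_predictors(),
                                         max_degree = 2) {
  if (inherits(patients, "imputed_stack")) {
    wins <- vapply(patients$copies, function(cp) {
      fp <- select_fractional_polynomial(cp, outcomes, variable,
                                         predictors, max_degree)
      paste(fp$powers, collapse = ",")
    }, character(1))
    tab <- table(wins)
    best <- names(tab)[tab == max(tab)]
    # ties: lower order, then closest to linear
    key <- lapply(strsplit(best, ","), as.numeric)
    ord <- order(lengths(key),
                 vapply(key, function(p) sum(abs(p - 1)), numeric(1)))
    pw <- key[[ord[1]]]
    sh <- fp_shift_for(patients$copies[[1]][[variable]])
    return(fp_transform(variable, pw, shift = sh))
  }
  x <- patients[[variable]]
  shift <- fp_shift_for(x)
  dev_for <- function(pw) {
    tr <- list(fp_transform(variable, pw, shift = shift))
    names(tr) <- variable
    fit_deviance(patients, outcomes, tr, predictors)
  }
  p1 <- fp1_powers()
  dev1 <- vapply(p1, dev_for, numeric(1))
  dev_lin <- dev1[p1 == 1]
  best1 <- p1[which.min(dev1)]
  pw <- if (dev_lin - min(dev1) > stats::qchisq(0.95, 1)) best1 else 1
  if (max_degree >= 2) {
    p2 <- fp2_powers()
    dev2 <- vapply(p2, dev_for, numeric(1))
    if (min(dev1) - min(dev2) > stats::qchisq(0.95, 2))
      pw <- p2[[which.min(dev2)]]
  }
  fp_transform(variable, pw, shift = shift)
}

#' Weighted Schoenfeld residuals of a Fine-Gray fit
#'
#' For each cause-1 event at time \eqn{t_j}, the residual is
#' \eqn{w_j\{x_j - \bar x(t_j)\}} with \eqn{\bar x(t_j)} the
#' exp(LP)-and-IPCW-weighted mean of the covariate over the risk set
#' (Breslow convention). The residuals sum to the weighted partial
#' likelihood score, which is zero at the maximum.
#'
#' @param model an `fg_model` fitted with `keep_fit = TRUE`.
#' @return List with `time` (event times, ascending) and `residuals`
#'   (matrix, one row per cause-1 event, one column per covariate).
#' @export
schoenfeld_residuals <- function(model) {
  fit <- model$fit
  if (is.null(fit) || is.null(fit$x))
    stop("model must be fitted with keep_fit = TRUE")
  Y <- as.matrix(fit$y)
  start <- Y[, 1]; stp <- Y[, 2]; status <- Y[, 3]
  X <- fit$x
  w <- if (is.null(fit$weights)) rep(1, nrow(X)) else fit$weights
  r <- w * exp(fit$linear.predictors)
  evt <- which(status == 1)
  evt <- evt[order(stp[evt])]
  res <- matrix(NA_real_, length(evt), ncol(X),
                dimnames = list(NULL, names(model$coefficients)))
  for (k in seq_along(evt)) {
    tj <- stp[evt[k]]
    R <- start < tj & stp >= tj
    xbar <- colSums(X[R, , drop = FALSE] * r[R]) / sum(r[R])
    res[k, ] <- w[evt[k]] * (X[evt[k], ] - xbar)
  }
  list(time = stp[evt], residuals = res)
}

#' Proportional subdistribution hazards diagnostic
#'
#' Computes weighted Schoenfeld-type residuals of the Fine-Gray fit at
#' cause-1 event times and, per covariate, the correlation of the residuals
#' with event-time rank together with a two-sided test of zero correlation.
#' A small p-value flags a time-varying effect, i.e. a violation of the
#' proportional subdistribution hazards assumption.
#'
#' @param model an `fg_model` fitted with `keep_fit = TRUE`.
#' @param alpha flagging level.
#' @return Data frame with one row per covariate: `rho`, `p_value`, `flag`.
#' @export
schoenfeld_check <- function(model, alpha = 0.05) {
  if (is.null(model$fit))
    stop("model must be fitted with keep_fit = TRUE")
  if (model$n_events < 2) stop("at least two cause-1 events required")
  sr <- schoenfeld_residuals(model)
  res <- sr$residuals
  r <- rank(sr$time)
  out <- do.call(rbind, lapply(seq_len(ncol(res)), function(j) {
    ct <- suppressWarnings(stats::cor.test(res[, j], r))
    data.frame(covariate = names(model$coefficients)[j],
               rho = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  out$flag <- out$p_value < alpha
  rownames(out) <- NULL
  out
}
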