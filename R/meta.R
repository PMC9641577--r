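#' REML random-effects meta-analysis of practice effects
#'
#' Pools k per-practice effect estimates under the random-effects model
#' \eqn{y_j \sim N(\mu, se_j^2 + \tau^2)}, with the between-practice
#' variance \eqn{\tau^2} estimated by restricted maximum likelihood (via
#' `metafor::rma`). The pooled estimate is the inverse-variance weighted
#' mean with weights \eqn{1/(se_j^2 + \hat\tau^2)}.
#'
#' @param effects numeric vector of practice-level effects (on the pooling
#'   scale).
#' @param ses their standard errors (> 0).
#' @param tau2_ci if `TRUE`, also compute a profile-likelihood confidence
#'   interval for \eqn{\tau^2}.
#' @return List with `pooled`, `se`, `tau2`, `k`, `ci` (95% CI for the
#'   pooled effect) and optionally `tau2_ci`.
#' @export
reml_random_effects <- function(effects, ses, tau2_ci = FALSE) {
  k <- length(effects)
  if (k < 2) stop("at least two practices required")
  if (length(ses) != k || any(ses <= 0)) stop("ses must be positive")
  fit <- metafor::rma(yi = effects, sei = ses, method = "REML",
                      control = list(threshold = 1e-10, maxiter = 1000))
  out <- list(pooled = as.numeric(fit$beta), se = fit$se, tau2 = fit$tau2,
              k = k, ci = c(fit$ci.lb, fit$ci.ub))
  if (tau2_ci) {
    ci <- tryCatch(metafor::confint.rma.uni(fit)$random,
                   error = function(e) NULL)
    out$tau2_ci <- if (is.null(ci)) c(NA_real_, NA_real_) else
      unname(ci["tau^2", c("ci.lb", "ci.ub")])
  }
  out
}

#' Meta-analytic prediction interval
#'
#' 95% interval expected to contain the true effect in a new practice:
#' \eqn{\hat\mu \pm t_{k-2,0.975}\sqrt{\hat\tau^2 + SE(\hat\mu)^2}}
#' (Higgins-Thompson convention), on the pooling scale.
#'
#' @param pooled pooled effect.
#' @param se its standard error.
#' @param tau2 between-practice variance.
#' @param k number of practices (>= 3).
#' @return `c(lower, upper)`.
#' @export
prediction_interval <- function(pooled, se, tau2, k) {
  if (k < 3) stop("prediction interval requires k >= 3")
  hw <- stats::qt(0.975, k - 2) * sqrt(tau2 + se^2)
  c(pooled - hw, pooled + hw)
}

#' Pool a per-practice metric by random-effects meta-analysis
#'
#' Transforms each practice's estimate to the pooling scale -- the
#' observed:expected ratio to \eqn{\ln(O/E)}, the C statistic to
#' \eqn{\mathrm{logit}(C)} with delta-method standard error
#' \eqn{SE(C)/\{C(1-C)\}}, the D statistic unchanged -- pools with
#' [reml_random_effects()], and back-transforms the pooled estimate with
#' its confidence and prediction intervals. Practices failing the
#' transform (O <= 0 for the log scale, C in \{0, 1\} for the logit scale,
#' missing SEs) or flagged `excluded` are dropped and counted.
#'
#' @param perf a [per_practice_performance()] table.
#' @param metric one of `"oe"`, `"c"`, `"d"`.
#' @param tau2_ci compute a profile-likelihood CI for \eqn{\tau^2}.
#' @return Object of class `meta_result`: metric, scale, `pooled`, `ci`,
#'   `pi` (prediction interval), `tau2` (with CI when requested), `k`,
#'   `n_dropped`.
#' @export
pool_metric <- function(perf, metric = c("oe", "c", "d"),
                        tau2_ci = FALSE) {
  metric <- match.arg(metric)
  perf <- perf[!perf$excluded, , drop = FALSE]
  tr <- switch(metric,
    oe = {
      ok <- is.finite(perf$oe) & perf$oe > 0 & is.finite(perf$se_log_oe)
      list(y = log(perf$oe[ok]), s = perf$se_log_oe[ok],
           back = exp, scale = "log")
    },
    c = {
      ok <- is.finite(perf$c) & perf$c > 0 & perf$c < 1 &
        is.finite(perf$se_c) & perf$se_c > 0
      list(y = stats::qlogis(perf$c[ok]),
           s = perf$se_c[ok] / (perf$c[ok] * (1 - perf$c[ok])),
           back = stats::plogis, scale = "logit")
    },
    d = {
      ok <- is.finite(perf$d) & is.finite(perf$se_d) & perf$se_d > 0
      list(y = perf$d[ok], s = perf$se_d[ok], back = identity,
           scale = "identity")
    })
  k <- length(tr$y)
  if (k < 2) stop("fewer than two poolable practices for ", metric)
  re <- reml_random_effects(tr$y, tr$s, tau2_ci = tau2_ci)
  pi_raw <- if (k >= 3)
    prediction_interval(re$pooled, re$se, re$tau2, k) else c(NA, NA)
  structure(list(metric = metric, scale = tr$scale,
                 pooled = tr$back(re$pooled), ci = tr$back(re$ci),
                 pi = tr$back(pi_raw), tau2 = re$tau2,
                 tau2_ci = re$tau2_ci, se_scale = re$se,
                 pooled_scale = re$pooled, k = k,
                 n_dropped = nrow(perf) - k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "%s pooled over %d practices (%s scale): %.3f (95%% CI %.3f to %.3f)\n",
    toupper(x$metric), x$k, x$scale, x$pooled, x$ci[1], x$ci[2]))
  cat(sprintf("  95%% prediction interval %.3f to %.3f; tau^2 = %.4f\n",
              x$pi[1], x$pi[2], x$tau2))
  if (x$n_dropped > 0) cat("  dropped", x$n_dropped,
                           "practices failing the transform\n")
  invisible(x)
}
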