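theta_of <- function(pseudo) if (is.data.frame(pseudo)) pseudo$theta else
  as.numeric(pseudo)

#' Observed:expected ratio against pseudo-value observed risks
#'
#' Calibration-in-the-large: O is the mean pseudo-value (the estimated
#' observed cumulative incidence) and E the mean predicted risk. A ratio
#' above 1 indicates under-prediction. The standard error is reported on
#' the log scale, \eqn{SE(\ln O/E) = sd(\theta)/(O\sqrt n)}, treating E as
#' fixed.
#'
#' @param pseudo pseudo-value set or numeric vector.
#' @param predicted predicted risks aligned with `pseudo`.
#' @return List with `oe`, `se_log`, `O`, `E`, `n` and `valid_log`
#'   (`FALSE` when O <= 0, in which case the practice is excluded from
#'   log-scale pooling).
#' @export
observed_expected_ratio <- function(pseudo, predicted) {
  theta <- theta_of(pseudo)
  if (length(theta) != length(predicted)) stop("inputs must align")
  O <- mean(theta)
  E <- mean(predicted)
  if (E <= 0) stop("mean predicted risk must be positive")
  valid <- O > 0
  if (!valid) warning("mean pseudo-value <= 0; excluded from log pooling")
  list(oe = O / E,
       se_log = if (valid) stats::sd(theta) / (O * sqrt(length(theta)))
                else NA_real_,
       O = O, E = E, n = length(theta), valid_log = valid)
}

#' Harrell's C between pseudo-values and predicted risks
#'
#' Pairwise concordance over all patient pairs with distinct pseudo-values:
#' the fraction in which the patient with the larger pseudo-value also has
#' the larger predicted risk, with prediction ties counted one half.
#' Computed through `survival::concordance()`; the standard error is the
#' infinitesimal-jackknife (U-statistic) estimate.
#'
#' @param pseudo pseudo-value set or numeric vector.
#' @param predicted predicted risks.
#' @return List with `c` and `se`.
#' @export
harrell_c <- function(pseudo, predicted) {
  theta <- theta_of(pseudo)
  if (length(theta) != length(predicted)) stop("inputs must align")
  if (length(theta) < 2) stop("at least two patients required")
  if (stats::sd(predicted) == 0) {
    warning("all predictions identical; C = 0.5")
    return(list(c = 0.5, se = NA_real_))
  }
  fit <- survival::concordance(theta ~ predicted)
  list(c = unname(fit$concordance),
       se = sqrt(max(unname(fit$var), 0)))
}

#' Royston's D and its explained-variation statistic from pseudo-values
#'
#' Prognostic separation of the linear predictor: patients are converted to
#' rankits \eqn{z_i = \Phi^{-1}\{(\mathrm{rank}(LP_i) - 3/8)/(n + 1/4)\}}
#' and the pseudo-values are regressed on \eqn{z/\kappa}
#' (\eqn{\kappa = \sqrt{8/\pi}}) through the logit-link estimating
#' equations of [pseudo_glm()]; D is the resulting slope, on the model's
#' log-hazard-contrast scale. The explained variation is
#' \eqn{R^2_D = (D^2/\kappa^2) / (\pi^2/6 + D^2/\kappa^2)}.
#'
#' @param pseudo pseudo-value set or numeric vector.
#' @param lp per-patient linear predictor.
#' @return List with `d`, `se` and `r2`.
#' @export
royston_d <- function(pseudo, lp) {
  theta <- theta_of(pseudo)
  n <- length(theta)
  if (n < 10) stop("at least 10 patients required")
  if (length(lp) != n) stop("inputs must align")
  if (stats::sd(lp) == 0) {
    warning("constant linear predictor; D = 0")
    return(list(d = 0, se = NA_real_, r2 = 0))
  }
  kappa <- sqrt(8 / pi)
  z <- stats::qnorm((rank(lp, ties.method = "average") - 3 / 8) /
                      (n + 1 / 4)) / kappa
  fit <- pseudo_glm(theta, cbind(z = z))
  d <- unname(fit$coef["z"])
  list(d = d, se = sqrt(fit$vcov["z", "z"]), r2 = r2_from_d(d))
}

#' Explained variation from Royston's D
#'
#' Closed form \eqn{R^2_D = (D^2/\kappa^2)/(\pi^2/6 + D^2/\kappa^2)} with
#' \eqn{\kappa^2 = 8/\pi}.
#'
#' @param d D statistic value(s).
#' @return \eqn{R^2_D} in `[0, 1)`.
#' @export
r2_from_d <- function(d) {
  s <- d^2 / (8 / pi)
  s / (pi^2 / 6 + s)
}

#' Calibration curve of predicted risk against pseudo-value observed risk
#'
#' Group points are the (mean predicted risk, mean pseudo-value) pairs in
#' `n_groups` equal-count groups of predicted risk; the smooth curve is a
#' local linear regression (loess, fixed span) of the pseudo-values on
#' predicted risk with a pointwise 95% band. A histogram of the predicted
#' risks accompanies the curve.
#'
#' @param pseudo pseudo-value set or numeric vector.
#' @param predicted predicted risks.
#' @param n_groups number of risk groups (default 10, i.e. deciles).
#' @param span loess span.
#' @return Object of class `calibration_curve`: list with `points` (group
#'   means), `smooth` (grid, fit, lower, upper), `hist` (breaks, counts).
#' @export
calibration_curve <- function(pseudo, predicted, n_groups = 10,
                              span = 0.75) {
  theta <- theta_of(pseudo)
  n <- length(theta)
  if (length(predicted) != n) stop("inputs must align")
  if (n_groups > n) stop("more groups than patients")
  if (stats::sd(predicted) == 0) {
    pts <- data.frame(predicted = mean(predicted), observed = mean(theta),
                      n = n)
    return(structure(list(points = pts, smooth = NULL,
                          hist = graphics::hist(predicted, plot = FALSE)),
                     class = "calibration_curve"))
  }
  ord <- order(predicted, seq_len(n))
  g <- integer(n)
  g[ord] <- ceiling(seq_len(n) * n_groups / n)
  pts <- data.frame(
    predicted = tapply(predicted, g, mean),
    observed = tapply(theta, g, mean),
    n = as.integer(table(g)))
  lo <- stats::loess(theta ~ predicted, degree = 1, span = span)
  grid <- seq(stats::quantile(predicted, 0.01),
              stats::quantile(predicted, 0.99), length.out = 100)
  pr <- stats::predict(lo, newdata = data.frame(predicted = grid),
                       se = TRUE)
  smooth <- data.frame(predicted = grid, fit = pr$fit,
                       lower = pr$fit - 1.96 * pr$se.fit,
                       upper = pr$fit + 1.96 * pr$se.fit)
  structure(list(points = pts, smooth = smooth,
                 hist = graphics::hist(predicted, breaks = 30,
                                       plot = FALSE)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve:", nrow(x$points), "group points\n")
  print(round(x$points, 4))
  invisible(x)
}

#' Per-practice validation metrics
#'
#' Computes the observed:expected ratio, Harrell's C and Royston's D (with
#' its explained variation) within each general practice, against the
#' supplied pseudo-values. Practices with fewer than `min_events` cause-1
#' events or fewer than `min_n` patients are flagged `excluded` with a
#' reason and skipped by the meta-analytic pooling, since their metric
#' estimates are too unstable.
#'
#' @param patients patient data frame with `practice_id`.
#' @param outcomes outcome data frame aligned by `patient_id`.
#' @param pseudo pseudo-value set aligned with `patients`.
#' @param predicted predicted risks.
#' @param lp linear predictors.
#' @param min_events,min_n minimum-data rules.
#' @return Data frame of class `practice_performance`, one row per
#'   practice: sizes, event counts, each metric with its SE, `excluded`,
#'   `reason`.
#' @export
per_practice_performance <- function(patients, outcomes, pseudo, predicted,
                                     lp, min_events = 2, min_n = 20) {
  theta <- theta_of(pseudo)
  o <- outcomes[match(patients$patient_id, outcomes$patient_id), ]
  pr <- factor(patients$practice_id)
  rows <- lapply(levels(pr), function(pid) {
    idx <- which(pr == pid)
    ev <- sum(o$event[idx] == 1)
    base <- data.frame(practice_id = pid, n = length(idx), events = ev,
                       oe = NA_real_, se_log_oe = NA_real_, c = NA_real_,
                       se_c = NA_real_, d = NA_real_, se_d = NA_real_,
                       r2 = NA_real_, excluded = FALSE, reason = "",
                       stringsAsFactors = FALSE)
    if (length(idx) < min_n || ev < min_events) {
      base$excluded <- TRUE
      base$reason <- if (length(idx) < min_n) "too few patients" else
        "too few fall events"
      return(base)
    }
    oe <- observed_expected_ratio(theta[idx], predicted[idx])
    cc <- harrell_c(theta[idx], predicted[idx])
    dd <- tryCatch(royston_d(theta[idx], lp[idx]),
                   error = function(e) list(d = NA_real_, se = NA_real_,
                                            r2 = NA_real_))
    base$oe <- oe$oe
    base$se_log_oe <- oe$se_log
    base$c <- cc$c
    base$se_c <- cc$se
    base$d <- dd$d
    base$se_d <- dd$se
    base$r2 <- dd$r2
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("practice_performance", "data.frame")
  out
}
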