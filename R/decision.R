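#' Net benefit of a risk-guided treatment strategy at one threshold
#'
#' Classifies patients as treated when their predicted risk is at or above
#' the threshold probability `p_t`, estimates the event probability among
#' the treated by the mean pseudo-value (competing-risks consistent), and
#' returns \eqn{NB = \{TP - FP \cdot p_t/(1-p_t)\}/n}.
#'
#' @param pseudo pseudo-value set or numeric vector.
#' @param predicted predicted risks.
#' @param p_t threshold probability in (0, 1).
#' @return Net benefit (events prevented-equivalents per patient).
#' @export
net_benefit <- function(pseudo, predicted, p_t) {
  if (p_t <= 0 || p_t >= 1) stop("p_t must lie in (0, 1)")
  theta <- theta_of(pseudo)
  if (length(theta) != length(predicted)) stop("inputs must align")
  n <- length(theta)
  treated <- predicted >= p_t
  nt <- sum(treated)
  if (nt == 0) return(0)
  phat <- mean(theta[treated])
  tp <- nt * phat
  fp <- nt * (1 - phat)
  (tp - fp * p_t / (1 - p_t)) / n
}

#' Decision curve analysis under competing risks
#'
#' Net benefit of one or more model variants across a grid of threshold
#' probabilities, against the model-blind comparators: introducing falls
#' prevention measures for all patients (treat-all, whose net benefit is
#' \eqn{\hat F - (1-\hat F) p_t/(1-p_t)} with \eqn{\hat F} the mean
#' pseudo-value) and for none (treat-none, identically zero). For each
#' variant the range of thresholds at which it dominates both comparators
#' is reported; the prespecified 10% threshold is flagged in the output.
#'
#' @param pseudo pseudo-value set or numeric vector.
#' @param risks named list of predicted-risk vectors (one per model
#'   variant), or a single numeric vector.
#' @param grid threshold grid; default 0.5% steps over (0, 0.5].
#' @param highlight threshold of prespecified clinical interest.
#' @return Object of class `decision_curve`: data frame `curve` with one
#'   row per threshold (net benefit per variant, treat-all, treat-none),
#'   `dominant` (per-variant threshold ranges where the model beats both
#'   comparators), `prevalence`, `highlight`.
#' @export
decision_curve_analysis <- function(pseudo, risks,
                                    grid = seq(0.005, 0.5, by = 0.005),
                                    highlight = 0.10) {
  theta <- theta_of(pseudo)
  if (!is.list(risks)) risks <- list(model = risks)
  if (is.null(names(risks)) || any(names(risks) == ""))
    names(risks) <- paste0("model", seq_along(risks))
  fhat <- mean(theta)
  curve <- data.frame(threshold = grid,
                      treat_all = fhat - (1 - fhat) * grid / (1 - grid),
                      treat_none = 0)
  for (nm in names(risks))
    curve[[nm]] <- vapply(grid, function(p)
      net_benefit(theta, risks[[nm]], p), numeric(1))
  dominant <- lapply(names(risks), function(nm) {
    ok <- curve[[nm]] >= pmax(curve$treat_all, 0) &
      (curve[[nm]] > 0 | curve$treat_all > 0)
    if (!any(ok)) return(c(NA_real_, NA_real_))
    range(grid[ok])
  })
  names(dominant) <- names(risks)
  structure(list(curve = curve, dominant = dominant, prevalence = fhat,
                 highlight = highlight),
            class = "decision_curve")
}

#' @export
print.decision_curve <- function(x, ...) {
  cat(sprintf(
    "Decision curve over %d thresholds; pseudo-value prevalence %.4f\n",
    nrow(x$curve), x$prevalence))
  for (nm in names(x$dominant)) {
    r <- x$dominant[[nm]]
    if (anyNA(r)) cat(sprintf("  %s: never dominates both comparators\n",
                              nm))
    else cat(sprintf("  %s dominates both comparators for thresholds %.3f-%.3f\n",
                     nm, r[1], r[2]))
  }
  i <- which.min(abs(x$curve$threshold - x$highlight))
  cat(sprintf("  at the %.0f%% threshold: net benefit %s\n",
              100 * x$highlight,
              paste(sprintf("%s %.4f",
                            setdiff(names(x$curve),
                                    c("threshold", "treat_all",
                                      "treat_none")),
                            unlist(x$curve[i, setdiff(names(x$curve),
                                                      c("threshold",
                                                        "treat_all",
                                                        "treat_none"))])),
                    collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Cross-classification of falls risk against cardiovascular risk
#'
#' Counts patients in the 2x2 classification by falls risk and
#' cardiovascular disease risk at a shared threshold (default 10%). CVD
#' risks are exogenous inputs (for example from an established
#' cardiovascular risk calculator). Proportions are reported to one
#' decimal percent.
#'
#' @param falls_risk,cvd_risk aligned risk vectors in `[0, 1]`.
#' @param threshold shared high-risk threshold.
#' @return Object of class `risk_cross_table`: 2x2 `counts` matrix (rows:
#'   falls high/low; columns: CVD high/low), matching `percent` matrix,
#'   `n`.
#' @export
cross_classify <- function(falls_risk, cvd_risk, threshold = 0.10) {
  if (length(falls_risk) != length(cvd_risk))
    stop("risk vectors must have equal length")
  fh <- factor(falls_risk > threshold, levels = c(TRUE, FALSE),
               labels = c("falls high", "falls low"))
  ch <- factor(cvd_risk > threshold, levels = c(TRUE, FALSE),
               labels = c("cvd high", "cvd low"))
  counts <- table(fh, ch)
  structure(list(counts = unclass(counts),
                 percent = pct_round(unclass(counts),
                                     length(falls_risk)),
                 n = length(falls_risk), threshold = threshold),
            class = "risk_cross_table")
}

#' @export
print.risk_cross_table <- function(x, ...) {
  cat(sprintf("Risk cross-classification at the %.0f%% threshold (n = %d)\n",
              100 * x$threshold, x$n))
  print(x$counts)
  cat("percent:\n")
  print(x$percent)
  invisible(x)
}
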