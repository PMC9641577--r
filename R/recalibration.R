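#' Estimating-equation fit of a logit mean to pseudo-value responses
#'
#' Solves the generalised estimating equations for a logit-link mean
#' function \eqn{\mu = \mathrm{expit}(X\gamma)} with a constant working
#' variance, i.e. minimises \eqn{\sum_i (y_i - \mu_i)^2} by Gauss-Newton
#' with step halving. The constant working variance (rather than the
#' binomial one) is the standard choice for pseudo-observation regressions,
#' whose responses may legitimately lie outside `[0, 1]`; responses are
#' never clipped. Standard errors come from the working-independence
#' sandwich estimator.
#'
#' @param y responses (pseudo-values).
#' @param X covariate matrix (no intercept column; one is added).
#' @param maxit,tol Gauss-Newton iteration controls.
#' @return List with `coef` (intercept first), `vcov`, `fitted`, `iter`,
#'   `converged`.
#' @export
pseudo_glm <- function(y, X, maxit = 200, tol = 1e-10) {
  X <- as.matrix(X)
  n <- length(y)
  Z <- cbind(`(Intercept)` = 1, X)
  ys <- pmin(pmax(y, 0.001), 0.999)          # starting values only
  b <- stats::lm.fit(Z, stats::qlogis(ys))$coefficients
  b[is.na(b)] <- 0
  sse <- function(b) sum((y - stats::plogis(drop(Z %*% b)))^2)
  s0 <- sse(b)
  step_norm <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% b)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    J <- Z * w
    r <- y - mu
    A <- crossprod(J)
    step <- tryCatch(solve(A, crossprod(J, r)),
                     error = function(e) stop(
                       "singular working information in pseudo_glm"))
    lam <- 1
    repeat {
      b_new <- b + lam * drop(step)
      s1 <- sse(b_new)
      if (s1 <= s0 + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    step_norm <- sqrt(sum((lam * step)^2))
    b <- b_new
    s0 <- s1
    if (step_norm < tol) break
  }
  if (step_norm >= sqrt(tol))
    stop(sprintf("pseudo_glm did not converge (final step norm %.3g)",
                 step_norm))
  eta <- drop(Z %*% b)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  J <- Z * w
  A <- crossprod(J)
  Bm <- crossprod(J * (y - mu))
  Ai <- solve(A)
  V <- Ai %*% Bm %*% Ai
  dimnames(V) <- list(colnames(Z), colnames(Z))
  list(coef = stats::setNames(b, colnames(Z)), vcov = V, fitted = mu,
       iter = it, converged = TRUE)
}

#' Recalibrate model predictions to observed pseudo-values
#'
#' Fits a horizon-specific recalibration of the falls model: the observed
#' pseudo-values are regressed on the original linear predictor through a
#' logit-link mean with constant working variance ([pseudo_glm()]). The
#' linear predictor is the only covariate; optionally its functional form is
#' chosen by a fractional polynomial search (FP1/FP2 over the shifted LP,
#' with an F-test preference for lower-order forms), allowing a non-linear
#' recalibration map. The original predictor coefficients are untouched;
#' only the intercept and shape of the risk map change.
#'
#' @param pseudo a [grouped_pseudovalues()] result or numeric vector of
#'   pseudo-values.
#' @param lp per-patient original linear predictor, aligned with `pseudo`.
#' @param horizon horizon label carried in the model (years).
#' @param fp_search if `TRUE`, search FP1/FP2 transforms of the LP; default
#'   uses the identity term only.
#' @return An object of class `recalibration_model`: `horizon`, `gamma`
#'   (coefficients, intercept first), `vcov`, `fp` (an [fp_transform()] or
#'   `NULL` for identity), `shift`.
#' @export
fit_recalibration <- function(pseudo, lp, horizon = NULL,
                              fp_search = FALSE) {
  theta <- if (is.data.frame(pseudo)) pseudo$theta else pseudo
  if (is.null(horizon) && !is.null(attr(pseudo, "horizon")))
    horizon <- attr(pseudo, "horizon")
  if (length(theta) != length(lp)) stop("pseudo and lp must align")
  if (stats::sd(lp) == 0) stop("linear predictor is constant")
  shift <- fp_shift_for(lp)
  fits <- list(identity = list(fp = NULL,
                               fit = pseudo_glm(theta, cbind(lp = lp))))
  if (fp_search) {
    n <- length(theta)
    sse_of <- function(f) sum((theta - f$fit$fitted)^2)
    best_of <- function(cands) {
      res <- lapply(cands, function(pw) {
        fp <- fp_transform("lp", pw, shift = shift)
        tryCatch(list(fp = fp, fit = pseudo_glm(theta, fp_eval(lp, fp))),
                 error = function(e) NULL)  # ill-conditioned candidate
      })
      res <- Filter(Negate(is.null), res)
      if (!length(res)) return(NULL)
      res[[which.min(vapply(res, sse_of, numeric(1)))]]
    }
    b1 <- best_of(fp1_powers())
    b2 <- best_of(fp2_powers())
    pick <- fits$identity
    # F-test style preference for the simpler map
    ftest <- function(simple, complex, df) {
      s0 <- sse_of(simple); s1 <- sse_of(complex)
      p <- length(complex$fit$coef)
      ((s0 - s1) / df) / (s1 / (n - p)) > stats::qf(0.95, df, n - p)
    }
    if (!is.null(b1) && ftest(pick, b1, 1)) pick <- b1
    if (!is.null(b2) && ftest(pick, b2, if (is.null(pick$fp)) 2 else
              3 - length(pick$fp$powers))) pick <- b2
    fits$chosen <- pick
  }
  chosen <- if (fp_search) fits$chosen else fits$identity
  structure(list(horizon = horizon, gamma = chosen$fit$coef,
                 vcov = chosen$fit$vcov, fp = chosen$fp, shift = shift),
            class = "recalibration_model")
}

#' @export
print.recalibration_model <- function(x, ...) {
  cat(sprintf("Pseudo-value recalibration at %s years: ",
              format(x$horizon)))
  if (is.null(x$fp)) cat("identity LP term\n") else
    cat(sprintf("FP powers (%s)\n", paste(x$fp$powers, collapse = ", ")))
  print(round(x$gamma, 4))
  invisible(x)
}

#' Apply a recalibration model to linear predictors
#'
#' @param model a `recalibration_model`.
#' @param lp original linear predictors.
#' @return Recalibrated risks in (0, 1). When the fitted map is monotone
#'   over the observed LP range, the ranking of patients is preserved.
#' @export
apply_recalibration <- function(model, lp) {
  Z <- if (is.null(model$fp)) cbind(lp = lp) else fp_eval(lp, model$fp)
  stats::plogis(drop(cbind(1, Z) %*% model$gamma))
}
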