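# counts per distinct follow-up time: at-risk n_j, cause-1/cause-2 events
event_counts <- function(time, event) {
  ut <- sort(unique(time))
  d1 <- vapply(ut, function(s) sum(time == s & event == 1), numeric(1))
  d2 <- vapply(ut, function(s) sum(time == s & event == 2), numeric(1))
  left <- vapply(ut, function(s) sum(time == s), numeric(1))
  n_at_risk <- length(time) - c(0, cumsum(left)[-length(ut)])
  list(ut = ut, d1 = d1, d2 = d2, n = n_at_risk)
}

# Aalen-Johansen cause-1 CIF from counts, evaluated at horizons t
f1_from_counts <- function(cnt, t) {
  ok <- cnt$n > 0
  ut <- cnt$ut[ok]; d1 <- cnt$d1[ok]; d2 <- cnt$d2[ok]; n <- cnt$n[ok]
  # all-cause Kaplan-Meier left limit S(t_j-)
  s_left <- cumprod(c(1, (1 - (d1 + d2) / n)[-length(n)]))
  inc <- s_left * d1 / n
  cum <- cumsum(inc)
  vapply(t, function(s) {
    j <- sum(ut <= s)
    if (j == 0) 0 else cum[j]
  }, numeric(1))
}

#' Aalen-Johansen cumulative incidence of a fall
#'
#' Nonparametric cumulative incidence of the cause-1 event in the presence
#' of the competing cause, \eqn{\hat F_1(t) = \sum_{t_j \le t}
#' \hat S(t_j-) d_{1j}/n_j}, with \eqn{\hat S} the all-cause Kaplan-Meier
#' estimate.
#'
#' @param outcomes data frame with `time` and `event` (0/1/2).
#' @param t horizon(s), years; must be positive.
#' @return \eqn{\hat F_1(t)}, vectorised over `t`.
#' @export
aalen_johansen_cif <- function(outcomes, t) {
  if (nrow(outcomes) == 0) stop("empty outcome data")
  check_outcomes(outcomes)
  if (any(t <= 0)) stop("t must be positive")
  f1_from_counts(event_counts(outcomes$time, outcomes$event), t)
}

#' Jackknife pseudo-values of the cumulative incidence of a fall
#'
#' Computes \eqn{\theta_i = n \hat F_1(t) - (n-1) \hat F_1^{(-i)}(t)}, the
#' jackknife contribution of each patient to the Aalen-Johansen cumulative
#' incidence at horizon `t`. Pseudo-values act as an individual-level
#' "observed outcome" under right censoring and competing risks; they may
#' legitimately fall outside `[0, 1]`. Patients sharing a follow-up time and
#' event type share a pseudo-value, so the leave-one-out estimates are
#' recomputed once per distinct (time, event) class; the result equals the
#' brute-force leave-one-out computation exactly.
#'
#' @param outcomes data frame with `time` and `event`.
#' @param t a single horizon, years.
#' @return Numeric vector of pseudo-values in patient order.
#' @export
jackknife_pseudovalues <- function(outcomes, t) {
  check_outcomes(outcomes)
  stopifnot(length(t) == 1, t > 0)
  n <- nrow(outcomes)
  if (n < 2) stop("at least two patients are required")
  time <- outcomes$time; event <- outcomes$event
  cnt <- event_counts(time, event)
  f_full <- f1_from_counts(cnt, t)
  key <- paste(match(time, cnt$ut), event)
  rep_idx <- which(!duplicated(key))
  f_loo <- vapply(rep_idx, function(i) {
    s <- time[i]; e <- event[i]
    c2 <- cnt
    j <- match(s, c2$ut)
    if (e == 1) c2$d1[j] <- c2$d1[j] - 1
    if (e == 2) c2$d2[j] <- c2$d2[j] - 1
    c2$n <- c2$n - (c2$ut <= s)
    f1_from_counts(c2, t)
  }, numeric(1))
  unname(n * f_full - (n - 1) * f_loo[match(key, key[rep_idx])])
}

#' Grouped pseudo-values by linear predictor
#'
#' Ranks patients by linear predictor, splits them into `n_groups`
#' equal-count groups (sizes differing by at most one; ties broken by stable
#' patient order) and computes jackknife pseudo-values within each group
#' independently, for numerical stability of the downstream calibration
#' regressions. Groups left with fewer than two members are merged with
#' their neighbour. If a group's largest follow-up time falls short of the
#' horizon, its pseudo-values are computed at the last attainable time and a
#' warning is issued.
#'
#' @param outcomes outcome data frame (`patient_id`, `time`, `event`).
#' @param lp per-patient linear predictor, aligned with `outcomes`.
#' @param t horizon, years.
#' @param n_groups number of groups (default 50; 1 reproduces the ungrouped
#'   jackknife).
#' @return An object of class `pseudo_value_set`: data frame with
#'   `patient_id`, `group`, `theta`, plus attributes `horizon` and
#'   `group_cif` (per-group Aalen-Johansen estimates).
#' @export
grouped_pseudovalues <- function(outcomes, lp, t, n_groups = 50) {
  check_outcomes(outcomes)
  if (n_groups < 1) stop("n_groups must be at least 1")
  n <- nrow(outcomes)
  if (length(lp) != n) stop("lp must align with outcomes")
  n_groups <- min(n_groups, floor(n / 2))
  n_groups <- max(n_groups, 1L)
  ord <- order(lp, seq_len(n))
  g <- integer(n)
  g[ord] <- ceiling(seq_len(n) * n_groups / n)
  # merge any group with fewer than 2 members into its lower neighbour
  repeat {
    sz <- table(g)
    small <- names(sz)[sz < 2]
    if (!length(small) || length(unique(g)) == 1) break
    s <- as.integer(small[1])
    g[g == s] <- if (s > min(g)) s - 1L else s + 1L
    g <- match(g, sort(unique(g)))  # relabel 1..k
  }
  groups <- sort(unique(g))
  theta <- numeric(n)
  gcif <- numeric(length(groups))
  for (k in seq_along(groups)) {
    idx <- which(g == groups[k])
    oc <- outcomes[idx, , drop = FALSE]
    tk <- t
    if (max(oc$time) < t) {
      tk <- max(oc$time)
      warning(sprintf(
        "group %d: horizon %g beyond last observed time; using %g",
        groups[k], t, tk))
    }
    theta[idx] <- jackknife_pseudovalues(oc, tk)
    gcif[k] <- aalen_johansen_cif(oc, tk)
  }
  structure(data.frame(patient_id = outcomes$patient_id, group = g,
                       theta = theta),
            horizon = t, group_cif = gcif, class = c("pseudo_value_set",
                                                     "data.frame"))
}
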