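#' Percentage from a count, rounded half-up to one decimal
#'
#' Matches the presentation convention of cohort description tables:
#' \eqn{100 \cdot count/denominator}, rounded half-up to one decimal place
#' (so 3.5366 prints as 3.5 and 10.2523 as 10.3).
#'
#' @param count,denominator counts (vectorised).
#' @return Numeric percentage(s) with one decimal.
#' @export
pct_round <- function(count, denominator) {
  floor(100 * count / denominator * 10 + 0.5) / 10
}

summ_num <- function(x) c(mean = mean(x, na.rm = TRUE),
                          sd = stats::sd(x, na.rm = TRUE))

summ_cat <- function(x, levels_, n) {
  x <- as.character(x)
  lv <- c(levels_, "missing")
  x[is.na(x)] <- "missing"
  cnt <- vapply(lv, function(l) sum(x == l), numeric(1))
  data.frame(level = lv, count = cnt, percent = pct_round(cnt, n),
             row.names = NULL)
}

#' Descriptive cohort summary stratified by 10-year outcome
#'
#' Computes the descriptive table of the cohort: per-variable means (SD)
#' or counts (percentages, one decimal, missing as its own category), in
#' the full cohort and stratified by outcome type at the horizon (fall,
#' competing death), plus event counts and median (IQR) follow-up.
#'
#' @param patients patient data frame.
#' @param outcomes outcome data frame.
#' @param horizon stratification horizon, years.
#' @return Object of class `cohort_summary`: list of per-stratum summaries
#'   (`total`, `falls`, `deaths`), `events` (counts and one-decimal
#'   percentages by type), `followup` (median, q1, q3).
#' @export
summarize_cohort <- function(patients, outcomes, horizon = 10) {
  o <- outcomes[match(patients$patient_id, outcomes$patient_id), ]
  strata <- list(total = rep(TRUE, nrow(patients)),
                 falls = o$event == 1 & o$time <= horizon,
                 deaths = o$event == 2 & o$time <= horizon)
  one <- function(keep) {
    p <- patients[keep, , drop = FALSE]
    n <- nrow(p)
    num <- c("age", "cholesterol", "sbp", "dbp", "frailty_index")
    num <- intersect(num, names(p))
    cats <- list(sex = c("female", "male"),
                 ethnicity = cat_levels$ethnicity,
                 imd_quintile = as.character(1:5),
                 smoking = cat_levels$smoking,
                 alcohol = cat_levels$alcohol)
    cats <- cats[names(cats) %in% names(p)]
    flags <- intersect(names(p), c(
      "previous_falls", "memory_problems", "mobility_problems", "stroke",
      "multiple_sclerosis", "acei", "arb", "alpha_blocker", "beta_blocker",
      "ccb", "diuretic", "other_antihypertensive", "opioid",
      "hypnotic_anxiolytic", "antidepressant", "anticholinergic"))
    list(n = n,
         numeric = if (n) t(vapply(num, function(v) summ_num(p[[v]]),
                                   numeric(2))) else NULL,
         categorical = stats::setNames(
           lapply(names(cats), function(v) summ_cat(p[[v]], cats[[v]], max(n, 1))),
           names(cats)),
         flags = if (n) data.frame(
           flag = flags,
           count = vapply(flags, function(v) sum(p[[v]]), numeric(1)),
           percent = pct_round(vapply(flags, function(v) sum(p[[v]]),
                                      numeric(1)), max(n, 1)),
           row.names = NULL) else NULL)
  }
  n <- nrow(patients)
  ev <- vapply(strata[c("falls", "deaths")], sum, numeric(1))
  fu <- stats::quantile(o$time, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(strata = lapply(strata, one),
                 events = data.frame(type = c("fall", "death"),
                                     count = as.integer(ev),
                                     percent = pct_round(ev, n)),
                 followup = list(median = fu[2], q1 = fu[1], q3 = fu[3]),
                 n = n, horizon = horizon),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients; %d-year outcome strata\n", x$n,
              x$horizon))
  print(x$events)
  cat(sprintf("median follow-up %.1f (IQR %.1f-%.1f) years\n",
              x$followup$median, x$followup$q1, x$followup$q3))
  invisible(x)
}
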