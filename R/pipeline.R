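#' Write / read a cohort as delimited text
#'
#' One row per patient (predictors plus `time` and `event`), tab-separated,
#' empty field = missing, with a commented header recording the format
#' version and the generating seed.
#'
#' @param cohort a `cohort_sim` or a list with `patients` and `outcomes`.
#' @param path file path.
#' @param seed seed recorded in the header (taken from the cohort config
#'   when present).
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  if (is.null(seed)) seed <- cohort$config$seed
  o <- cohort$outcomes[match(cohort$patients$patient_id,
                             cohort$outcomes$patient_id), ]
  df <- cbind(cohort$patients, time = o$time, event = o$event)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# crfalls cohort v1",
               paste0("# seed: ", if (is.null(seed)) "NA" else seed)), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @return `read_cohort()` returns a list with `patients`, `outcomes`,
#'   `seed`.
#' @export
read_cohort <- function(path) {
  hdr <- readLines(path, n = 5)
  seed_line <- grep("^# seed:", hdr, value = TRUE)
  seed <- if (length(seed_line))
    suppressWarnings(as.integer(sub("^# seed: *", "", seed_line[1]))) else NA
  df <- utils::read.delim(path, comment.char = "#", na.strings = "",
                          stringsAsFactors = FALSE)
  list(patients = df[, setdiff(names(df), c("time", "event")),
                     drop = FALSE],
       outcomes = data.frame(patient_id = df$patient_id, time = df$time,
                             event = df$event),
       seed = seed)
}

tr_to_list <- function(tr) lapply(tr, function(f)
  list(powers = f$powers, shift = f$shift, scale = f$scale))

tr_from_list <- function(lst) {
  out <- lapply(names(lst), function(v)
    fp_transform(v, unlist(lst[[v]]$powers), shift = lst[[v]]$shift,
                 scale = lst[[v]]$scale))
  stats::setNames(out, names(lst))
}

#' Serialize a fitted model (and its recalibrations) to structured text
#'
#' Writes a versioned JSON model file containing the coefficient table
#' (name, transform, log-SHR, SE), covariate centering constants, the
#' baseline cumulative incidence as (time, value) pairs -- both the full
#' step grid and the values at the 1/5/10-year horizons -- and any
#' per-horizon pseudo-value recalibration models. Externally published
#' coefficient sets in the same layout can be loaded with [read_model()]
#' without code changes.
#'
#' @param model an `fg_model`.
#' @param path file path.
#' @param recalibration optional named list of `recalibration_model`s
#'   keyed by horizon.
#' @param horizons horizons at which the baseline CIF is tabulated.
#' @export
write_model <- function(model, path, recalibration = NULL,
                        horizons = c(1, 5, 10)) {
  obj <- list(
    format = "crfalls-model", version = "1",
    predictors = model$predictors,
    coefficients = as.list(model$coefficients),
    se = as.list(model$se),
    center = as.list(model$center),
    transforms = tr_to_list(model$transforms),
    baseline = list(time = model$baseline$time,
                    cif0 = model$baseline$cif0),
    baseline_at_horizons = list(horizon = horizons,
                                cif0 = baseline_cif_at(model, horizons)),
    n = model$n, n_events = model$n_events)
  if (!is.null(recalibration))
    obj$recalibration <- lapply(recalibration, function(r) {
      if (is.null(r)) return(NULL)
      list(horizon = r$horizon, gamma = as.list(r$gamma),
           fp = if (is.null(r$fp)) NULL else
             list(powers = r$fp$powers, shift = r$fp$shift,
                  scale = r$fp$scale),
           shift = r$shift)
    })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()` returns a list with `model` (an `fg_model`) and
#'   `recalibration` (named list, possibly empty).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "crfalls-model"))
    stop("not a crfalls model file")
  hz <- obj$baseline$cif0
  model <- structure(list(
    coefficients = unlist(obj$coefficients),
    se = unlist(obj$se),
    vcov = NULL,
    transforms = if (length(obj$transforms)) tr_from_list(obj$transforms)
                 else NULL,
    center = unlist(obj$center),
    baseline = data.frame(time = obj$baseline$time,
                          hazard = -log(1 - hz), cif0 = hz),
    predictors = obj$predictors, n = obj$n, n_events = obj$n_events,
    loglik = NA_real_, iter = NA_integer_, fit = NULL),
    class = "fg_model")
  recal <- list()
  if (!is.null(obj$recalibration))
    recal <- lapply(obj$recalibration, function(r) {
      if (is.null(r)) return(NULL)
      structure(list(horizon = r$horizon, gamma = unlist(r$gamma),
                     vcov = NULL,
                     fp = if (is.null(r$fp)) NULL else
                       fp_transform("lp", unlist(r$fp$powers),
                                    shift = r$fp$shift,
                                    scale = r$fp$scale),
                     shift = r$shift),
                class = "recalibration_model")
    })
  list(model = model, recalibration = recal)
}

pool_fits <- function(fits) {
  m <- length(fits)
  if (m == 1) return(fits[[1]])
  nms <- names(fits[[1]]$coefficients)
  est <- sapply(fits, function(f) f$coefficients[nms])
  vv <- sapply(fits, function(f) f$se[nms]^2)
  pooled <- lapply(seq_along(nms), function(j)
    rubin_pool(est[j, ], vv[j, ]))
  beta <- vapply(pooled, `[[`, numeric(1), "estimate")
  se <- sqrt(vapply(pooled, `[[`, numeric(1), "T"))
  names(beta) <- names(se) <- nms
  grid <- sort(unique(unlist(lapply(fits, function(f) f$baseline$time))))
  H <- rowMeans(sapply(fits, function(f)
    stats::stepfun(f$baseline$time, c(0, f$baseline$hazard))(grid)))
  center <- rowMeans(sapply(fits, function(f) f$center[nms]))
  structure(list(coefficients = beta, se = se, vcov = NULL,
                 transforms = fits[[1]]$transforms, center = center,
                 baseline = data.frame(time = grid, hazard = H,
                                       cif0 = 1 - exp(-H)),
                 predictors = fits[[1]]$predictors, n = fits[[1]]$n,
                 n_events = fits[[1]]$n_events,
                 loglik = NA_real_, iter = NA_integer_, fit = NULL,
                 pooled = pooled),
            class = "fg_model")
}

stack_or_single <- function(patients, outcomes, m, cycles, predictors,
                            seed) {
  if (any(vapply(intersect(imputable_vars, names(patients)),
                 function(v) anyNA(patients[[v]]), logical(1)))) {
    mice_impute(patients, outcomes, m = m, cycles = cycles,
                predictors = predictors, seed = seed)
  } else {
    structure(list(m = 1L, copies = list(patients),
                   methods = character(0), trace = NULL, seed = seed),
              class = "imputed_stack")
  }
}

#' Develop a falls prediction model end to end
#'
#' Orchestrates the development run: multiple imputation of missing
#' predictors (skipped when the cohort is complete), optional fractional
#' polynomial selection, per-imputation Fine-Gray fits pooled by Rubin's
#' rules (baseline cumulative hazards averaged across copies on the union
#' time grid), apparent calibration against grouped pseudo-values at each
#' horizon, and logit-link pseudo-value recalibration at the horizons that
#' need it.
#'
#' @param patients development patient table (may contain missing values
#'   in the imputable predictors).
#' @param outcomes outcome table.
#' @param horizons prediction horizons in years.
#' @param recalibrate_horizons horizons at which a recalibration model is
#'   fitted (per-horizon flags; a horizon whose apparent calibration is
#'   good can be left out).
#' @param m,cycles imputation settings (ignored for complete cohorts).
#' @param n_groups pseudo-value LP groups.
#' @param fp_vars continuous predictors whose functional form is searched
#'   by [select_fractional_polynomial()] (`NULL` keeps all linear).
#' @param fp_recal search FP terms in the recalibration maps.
#' @param predictors predictor set.
#' @param exclude predictors pruned by explicit choice.
#' @param seed seed for the imputation draws.
#' @return Object of class `dev_result`: `model` (pooled `fg_model`),
#'   `recalibration` (named by horizon), `apparent` (per horizon:
#'   observed:expected ratio and calibration curve, before and after
#'   recalibration), `coef_table`, `m`.
#' @export
run_development <- function(patients, outcomes, horizons = c(1, 5, 10),
                            recalibrate_horizons = c(5, 10),
                            m = 10, cycles = 10, n_groups = 50,
                            fp_vars = NULL, fp_recal = TRUE,
                            predictors = default_predictors(),
                            exclude = NULL, seed = 1L) {
  stack <- stack_or_single(patients, outcomes, m, cycles, predictors, seed)
  transforms <- NULL
  if (length(fp_vars)) {
    transforms <- stats::setNames(lapply(fp_vars, function(v)
      select_fractional_polynomial(stack, outcomes, v,
                                   predictors = setdiff(predictors,
                                                        exclude))),
      fp_vars)
  }
  fits <- lapply(stack$copies, function(cp)
    fit_finegray(cp, outcomes, transforms, predictors, exclude,
                 keep_fit = FALSE))
  model <- pool_fits(fits)

  rep_copy <- stack$copies[[1]]
  lp <- linear_predictor(model, rep_copy)
  recal <- list()
  apparent <- list()
  for (h in horizons) {
    psv <- grouped_pseudovalues(outcomes[match(rep_copy$patient_id,
                                               outcomes$patient_id), ],
                                lp, h, n_groups)
    risk <- predict_cif(model, t = h, lp = lp)
    app <- list(oe = observed_expected_ratio(psv, risk),
                curve = calibration_curve(psv, risk))
    if (h %in% recalibrate_horizons) {
      rc <- fit_recalibration(psv, lp, horizon = h, fp_search = fp_recal)
      recal[[as.character(h)]] <- rc
      risk2 <- apply_recalibration(rc, lp)
      app$oe_recal <- observed_expected_ratio(psv, risk2)
      app$curve_recal <- calibration_curve(psv, risk2)
    }
    apparent[[as.character(h)]] <- app
  }
  ct <- data.frame(term = names(model$coefficients),
                   coef = unname(model$coefficients),
                   shr = exp(unname(model$coefficients)),
                   se = unname(model$se))
  ct$shr_low <- exp(ct$coef - 1.96 * ct$se)
  ct$shr_high <- exp(ct$coef + 1.96 * ct$se)
  structure(list(model = model, recalibration = recal,
                 apparent = apparent, coef_table = ct, m = stack$m,
                 horizons = horizons, seed = seed),
            class = "dev_result")
}

#' @export
print.dev_result <- function(x, ...) {
  cat(sprintf("Development run: %d imputation(s), horizons %s\n", x$m,
              paste(x$horizons, collapse = "/")))
  print(x$model)
  for (h in names(x$recalibration)) {
    cat(sprintf("-- horizon %s --\n", h))
    print(x$recalibration[[h]])
  }
  invisible(x)
}

#' Predict falls risks for new patients
#'
#' Applies a (possibly recalibrated) falls model to a patient file. Binary
#' diagnosis/prescription flags absent from the table default to 0
#' (absence of a code means absence of the condition); any other
#' unresolvable predictor raises an error. Row order is preserved.
#'
#' @param model an `fg_model` (e.g. from [read_model()]).
#' @param patients patient table.
#' @param horizons horizons in years.
#' @param recalibration optional named list of recalibration models keyed
#'   by horizon (as produced by [run_development()]).
#' @return Data frame with `patient_id`, `horizon`, `risk` (original
#'   model) and, where a recalibration exists for the horizon,
#'   `risk_recalibrated`.
#' @export
predict_risks <- function(model, patients, horizons = c(1, 5, 10),
                          recalibration = NULL) {
  flag_vars <- setdiff(model$predictors,
                       c("age", "sex", "ethnicity", "imd_quintile",
                         "smoking", "alcohol", "cholesterol",
                         "frailty_index", "sbp", "dbp"))
  for (v in flag_vars) if (is.null(patients[[v]])) patients[[v]] <- 0
  lp <- linear_predictor(model, patients)
  any_recal <- length(recalibration) > 0
  out <- do.call(rbind, lapply(horizons, function(h) {
    d <- data.frame(patient_id = patients$patient_id, horizon = h,
                    risk = predict_cif(model, t = h, lp = lp))
    if (any_recal) {
      rc <- recalibration[[as.character(h)]]
      d$risk_recalibrated <- if (is.null(rc)) NA_real_ else
        apply_recalibration(rc, lp)
    }
    d
  }))
  rownames(out) <- NULL
  out
}

pool_meta_across <- function(metas) {
  if (length(metas) == 1) return(metas[[1]])
  est <- vapply(metas, `[[`, numeric(1), "pooled_scale")
  vv <- vapply(metas, function(x) x$se_scale^2, numeric(1))
  rp <- rubin_pool(est, vv)
  tau2 <- stats::median(vapply(metas, `[[`, numeric(1), "tau2"))
  k <- metas[[1]]$k
  back <- switch(metas[[1]]$scale, log = exp, logit = stats::plogis,
                 identity = identity)
  se_t <- sqrt(rp$T)
  ci <- back(rp$estimate + c(-1, 1) * stats::qt(0.975, rp$df) * se_t)
  pi_ <- back(prediction_interval(rp$estimate, se_t, tau2, k))
  structure(list(metric = metas[[1]]$metric, scale = metas[[1]]$scale,
                 pooled = back(rp$estimate), ci = ci, pi = pi_,
                 tau2 = tau2, tau2_ci = NULL, se_scale = se_t,
                 pooled_scale = rp$estimate, k = k,
                 n_dropped = metas[[1]]$n_dropped),
            class = "meta_result")
}

#' Externally validate a falls model
#'
#' Applies a developed model (original and, where available, recalibrated)
#' to an external cohort: multiple imputation when predictors are missing,
#' grouped pseudo-values per horizon, overall and per-practice performance
#' (observed:expected ratio, Harrell's C, Royston's D and explained
#' variation), REML random-effects pooling across practices with
#' prediction intervals, and decision-curve analysis. Scalar metrics are
#' combined across imputed copies by Rubin's rules on the pooling scales
#' (log O:E, logit C, raw D); the explained variation is summarised by
#' median and interquartile range.
#'
#' @param dev a `dev_result`, or a list with `model` and `recalibration`
#'   (e.g. from [read_model()]).
#' @param patients,outcomes external validation cohort.
#' @param horizons horizons in years.
#' @param m,cycles imputation settings for the validation cohort.
#' @param n_groups pseudo-value LP groups.
#' @param dca_grid decision-curve threshold grid.
#' @param seed imputation seed.
#' @return Object of class `val_result`: per horizon a list with
#'   `overall` (per-variant O:E, C, D, R2), `meta` (pooled per-practice
#'   metrics for the final variant), `curve` (calibration curve),
#'   `dca` (decision curves), `r2_summary`; plus `report`, a
#'   Table-style data frame (metric x horizon x variant).
#' @export
run_external_validation <- function(dev, patients, outcomes,
                                    horizons = c(1, 5, 10), m = 10,
                                    cycles = 10, n_groups = 50,
                                    dca_grid = seq(0.005, 0.5, 0.005),
                                    seed = 2L) {
  model <- dev$model
  recal <- dev$recalibration
  stack <- stack_or_single(patients, outcomes, m, cycles,
                           model$predictors, seed)
  o <- outcomes[match(patients$patient_id, outcomes$patient_id), ]
  res <- list()
  report <- NULL
  for (h in horizons) {
    hc <- as.character(h)
    rc <- recal[[hc]]
    per_copy <- lapply(stack$copies, function(cp) {
      lp <- linear_predictor(model, cp)
      psv <- grouped_pseudovalues(o, lp, h, n_groups)
      risks <- list(original = predict_cif(model, t = h, lp = lp))
      if (!is.null(rc)) risks$recalibrated <- apply_recalibration(rc, lp)
      final <- risks[[length(risks)]]
      overall <- lapply(risks, function(r) {
        oe <- observed_expected_ratio(psv, r)
        cc <- harrell_c(psv, r)
        dd <- royston_d(psv, lp)
        list(oe = oe, c = cc, d = dd)
      })
      perf <- per_practice_performance(cp, o, psv, final, lp)
      metas <- lapply(c(oe = "oe", c = "c", d = "d"), function(mt)
        tryCatch(pool_metric(perf, mt), error = function(e) NULL))
      list(lp = lp, psv = psv, risks = risks, overall = overall,
           perf = perf, metas = metas)
    })
    first <- per_copy[[1]]
    metas <- lapply(c(oe = "oe", c = "c", d = "d"), function(mt) {
      ms <- Filter(Negate(is.null),
                   lapply(per_copy, function(pc) pc$metas[[mt]]))
      if (!length(ms)) return(NULL)
      pool_meta_across(ms)
    })
    r2_all <- unlist(lapply(per_copy, function(pc)
      pc$perf$r2[!pc$perf$excluded]))
    r2_all <- r2_all[is.finite(r2_all)]
    r2_summary <- c(median_iqr_pool(100 * r2_all),
                    list(range = range(100 * r2_all)))
    final_name <- names(first$risks)[length(first$risks)]
    res[[hc]] <- list(
      overall = first$overall,
      overall_pooled = pool_overall(per_copy),
      meta = metas,
      perf = first$perf,
      curve = calibration_curve(first$psv,
                                first$risks[[final_name]]),
      dca = decision_curve_analysis(first$psv, first$risks,
                                    grid = dca_grid),
      r2_summary = r2_summary,
      final_variant = final_name)
    for (mt in names(metas)) if (!is.null(metas[[mt]]))
      report <- rbind(report, data.frame(
        horizon = h, variant = final_name, metric = mt,
        pooled = metas[[mt]]$pooled, ci_low = metas[[mt]]$ci[1],
        ci_high = metas[[mt]]$ci[2], pi_low = metas[[mt]]$pi[1],
        pi_high = metas[[mt]]$pi[2], tau2 = metas[[mt]]$tau2,
        k = metas[[mt]]$k))
  }
  structure(list(horizons = res, report = report, m = stack$m,
                 seed = seed),
            class = "val_result")
}

# Rubin-pool the overall (whole-cohort) metrics across imputed copies
pool_overall <- function(per_copy) {
  variants <- names(per_copy[[1]]$overall)
  out <- list()
  for (v in variants) {
    gets <- function(f) vapply(per_copy, function(pc) f(pc$overall[[v]]),
                               numeric(1))
    m <- length(per_copy)
    pool1 <- function(est, vv, back) {
      if (m == 1) return(back(est[1]))
      back(rubin_pool(est, vv)$estimate)
    }
    out[[v]] <- list(
      oe = pool1(log(gets(function(x) x$oe$oe)),
                 gets(function(x) x$oe$se_log)^2, exp),
      c = pool1(stats::qlogis(gets(function(x) x$c$c)),
                (gets(function(x) x$c$se) /
                   (gets(function(x) x$c$c) *
                      (1 - gets(function(x) x$c$c))))^2,
                stats::plogis),
      d = pool1(gets(function(x) x$d$d), gets(function(x) x$d$se)^2,
                identity),
      r2 = stats::median(gets(function(x) x$d$r2)))
  }
  out
}

#' @export
print.val_result <- function(x, ...) {
  cat(sprintf("External validation (%d imputation(s))\n", x$m))
  if (!is.null(x$report)) print(transform(x$report,
                                          pooled = round(pooled, 3),
                                          ci_low = round(ci_low, 3),
                                          ci_high = round(ci_high, 3),
                                          pi_low = round(pi_low, 3),
                                          pi_high = round(pi_high, 3),
                                          tau2 = round(tau2, 4)))
  invisible(x)
}
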