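#' Predictor sets and design matrices
#'
#' The default predictor set contains the 24 predictors of the falls model:
#' age, sex, ethnicity, deprivation quintile, smoking, alcohol, total
#' cholesterol, frailty index, five comorbidity flags and eleven
#' prescription flags. Systolic/diastolic blood pressure are carried in the
#' cohort but excluded from the default model, mirroring the pruning of
#' predictors with little or no adjusted association.
#'
#' @return Character vector of predictor (column) names in the patient table.
#' @export
default_predictors <- function() {
  c("age", "sex", "ethnicity", "imd_quintile", "smoking", "alcohol",
    "cholesterol", "frailty_index",
    "previous_falls", "memory_problems", "mobility_problems", "stroke",
    "multiple_sclerosis", "acei", "arb", "alpha_blocker", "beta_blocker",
    "ccb", "diuretic", "other_antihypertensive", "opioid",
    "hypnotic_anxiolytic", "antidepressant", "anticholinergic")
}

cat_levels <- list(
  ethnicity = c("white", "black", "south_asian", "other"),
  smoking = c("non", "former", "current"),
  alcohol = c("non", "occasional", "light", "moderate", "heavy",
              "unknown_amount"))

continuous_predictors <- function() c("age", "cholesterol", "frailty_index",
                                      "sbp", "dbp")

#' Fractional polynomial transform
#'
#' Represents an FP1 or FP2 transform of a positive variable. A power of 0
#' denotes the natural logarithm; a repeated power `(p, p)` denotes the pair
#' \eqn{x^p} and \eqn{x^p \ln x}. The variable is shifted and scaled to
#' `(x + shift)/scale` before the powers are applied, so transforms remain
#' defined for variables with non-positive support (for example a frailty
#' index of zero).
#'
#' @param variable name of the variable transformed.
#' @param powers numeric vector of length 1 (FP1) or 2 (FP2) with entries
#'   from \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}.
#' @param shift,scale positivity shift and scale applied before the powers.
#' @return An object of class `fp_transform`.
#' @export
fp_transform <- function(variable, powers = 1, shift = 0, scale = 1) {
  if (!length(powers) %in% 1:2) stop("powers must have length 1 or 2")
  if (!all(powers %in% c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)))
    stop("powers must come from {-2, -1, -0.5, 0, 0.5, 1, 2, 3}")
  structure(list(variable = variable, powers = powers,
                 shift = shift, scale = scale), class = "fp_transform")
}

#' @export
print.fp_transform <- function(x, ...) {
  cat(sprintf("FP%d(%s) powers (%s), shift %g, scale %g\n",
              length(x$powers), x$variable,
              paste(x$powers, collapse = ", "), x$shift, x$scale))
  invisible(x)
}

#' Evaluate a fractional polynomial transform
#'
#' @param x numeric vector.
#' @param fp an [fp_transform()].
#' @return Matrix with one column per FP term, named `<variable>_1` (and
#'   `<variable>_2` for FP2 terms).
#' @export
fp_eval <- function(x, fp) {
  z <- (x + fp$shift) / fp$scale
  if (any(z <= 0, na.rm = TRUE))
    stop("non-positive values after shift for ", fp$variable,
         "; increase the shift")
  pw <- fp$powers
  one <- function(p) if (p == 0) log(z) else z^p
  if (length(pw) == 1) {
    out <- cbind(one(pw[1]))
  } else if (pw[1] == pw[2]) {
    out <- cbind(one(pw[1]), one(pw[1]) * log(z))
  } else {
    out <- cbind(one(pw[1]), one(pw[2]))
  }
  colnames(out) <- paste0(fp$variable, "_", seq_len(ncol(out)))
  out
}

#' Build the model design matrix from a patient table
#'
#' Expands the patient table into the numeric design matrix of the falls
#' model: dummy coding for categorical predictors (reference levels white /
#' non-smoker / non-drinker / deprivation quintile 1 / male), binary flags
#' as 0/1, and continuous predictors either as identity columns or through
#' supplied fractional polynomial transforms.
#'
#' @param patients patient data frame.
#' @param transforms optional named list of [fp_transform()] objects keyed by
#'   continuous variable name.
#' @param predictors character vector of predictors to include.
#' @return Numeric matrix with one row per patient. Missing values
#'   propagate to `NA` entries.
#' @export
design_matrix <- function(patients, transforms = NULL,
                          predictors = default_predictors()) {
  unknown <- setdiff(predictors, names(patients))
  if (length(unknown))
    stop("unknown predictor columns: ", paste(unknown, collapse = ", "))
  cols <- list()
  for (v in predictors) {
    x <- patients[[v]]
    if (v == "sex") {
      cols[["sexfemale"]] <- as.numeric(x == "female")
    } else if (v == "imd_quintile") {
      for (k in 2:5) cols[[paste0("imd", k)]] <-
          ifelse(is.na(x), NA_real_, as.numeric(x == k))
    } else if (v %in% names(cat_levels)) {
      lv <- cat_levels[[v]]
      for (l in lv[-1]) cols[[paste0(v, l)]] <-
          ifelse(is.na(x), NA_real_, as.numeric(x == l))
    } else if (v %in% continuous_predictors() && !is.null(transforms) &&
               v %in% names(transforms)) {
      m <- fp_eval(x, transforms[[v]])
      for (j in seq_len(ncol(m))) cols[[colnames(m)[j]]] <- m[, j]
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}

fp1_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp2_powers <- function() {
  p <- fp1_powers()
  out <- list()
  for (i in seq_along(p)) for (j in i:length(p))
    out[[length(out) + 1]] <- c(p[i], p[j])
  out
}

# order used for "lower order wherever possible" tie-breaking:
# linear first, then remaining FP1 by distance from 1, then FP2
fp_candidates <- function() {
  p1 <- fp1_powers()
  p1 <- p1[order(abs(p1 - 1))]
  c(lapply(p1, identity), fp2_powers())
}
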