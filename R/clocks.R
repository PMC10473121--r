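#' Define a linear epigenetic clock
#'
#' An epigenetic clock is a weighted sum of CpG beta values plus an
#' intercept, optionally passed through a calibration transform. The
#' piecewise-log calibration is the standard adult-age-anchored form: for
#' latent value `x` and anchor `A` (default 20), ages below the anchor map
#' through `(1 + A) * exp(x) - 1` and above through `(1 + A) * x + A`; the
#' two branches agree at `x = 0` (both give `A`). Pace-of-aging scores are
#' supported by setting `is_age_estimator = FALSE` (identity calibration
#' required); their raw values are reported and no delta age is formed.
#'
#' @param name clock name.
#' @param intercept scalar intercept.
#' @param weights named numeric vector mapping probe IDs to coefficients
#'   (at least one).
#' @param calibration "identity" or "piecewise_log".
#' @param adult_age anchor age for the piecewise-log calibration.
#' @param is_age_estimator TRUE for clocks estimating age in years; FALSE
#'   for unitless pace scores.
#'
#' @return An object of class `clock_definition`.
#' @export
clock_definition <- function(name, intercept, weights,
                             calibration = c("identity", "piecewise_log"),
                             adult_age = 20, is_age_estimator = TRUE) {
  calibration <- match.arg(calibration)
  if (length(weights) < 1 || is.null(names(weights))) {
    stop_mp("weights must be a named vector with at least one coefficient")
  }
  if (!is.finite(intercept) || !is.finite(adult_age)) {
    stop_mp("clock parameters must be finite")
  }
  if (!is_age_estimator && calibration != "identity") {
    stop_mp("non-age-estimating clocks must use the identity calibration")
  }
  structure(list(name = name, intercept = intercept, weights = weights,
                 calibration = calibration, adult_age = adult_age,
                 is_age_estimator = is_age_estimator),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("Epigenetic clock '%s': %d CpGs, intercept %.4g, %s calibration%s\n",
              x$name, length(x$weights), x$intercept, x$calibration,
              if (x$is_age_estimator) "" else " (pace score, not an age)"))
  invisible(x)
}

clock_calibrate <- function(x, clock) {
  if (clock$calibration == "identity") return(x)
  A <- clock$adult_age
  ifelse(x < 0, (1 + A) * exp(x) - 1, (1 + A) * x + A)
}

#' Compute an epigenetic clock over a beta matrix
#'
#' Evaluates `calibration(intercept + sum(w_i * beta_i))` per sample. When
#' `allow_missing` is TRUE, clock CpGs absent from the matrix are dropped
#' (count reported via attribute `n_missing_cpgs`) and entries missing
#' within present clock CpGs are KNN-imputed first; when FALSE, any absent
#' clock CpG is an error.
#'
#' @param m CpG x sample beta matrix.
#' @param clock a [clock_definition()].
#' @param samples optional sample sheet with `sample_id` and `age` columns;
#'   when given, chronological and delta ages are filled in.
#' @param allow_missing tolerate missing clock CpGs (see Details).
#' @param k neighbours for the imputation of masked entries.
#'
#' @return A data.frame with `sample_id`, `clock`, `clock_value`, and (when
#'   ages are available) `age` and `delta_age` (NA for pace scores).
#' @export
compute_clock <- function(m, clock, samples = NULL, allow_missing = FALSE,
                          k = 10) {
  assert_beta_matrix(m)
  probes <- names(clock$weights)
  present <- probes %in% rownames(m)
  if (!any(present)) stop_mp("no clock CpGs present in the matrix")
  if (!allow_missing && !all(present)) {
    stop_mp(sum(!present), " clock CpG(s) absent from the matrix; ",
            "set allow_missing = TRUE to drop them")
  }
  use <- probes[present]
  sub <- m[use, , drop = FALSE]
  if (anyNA(sub)) {
    if (!allow_missing) stop_mp("clock CpGs contain missing values")
    sub <- knn_impute(sub, k = min(k, ncol(sub) - 1))
  }
  latent <- clock$intercept +
    as.numeric(crossprod(clock$weights[use], sub))
  res <- data.frame(sample_id = colnames(m), clock = clock$name,
                    clock_value = clock_calibrate(latent, clock),
                    stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    res$age <- samples$age[match(res$sample_id, samples$sample_id)]
    res <- delta_age(res, is_age_estimator = clock$is_age_estimator)
  }
  attr(res, "n_missing_cpgs") <- sum(!present)
  res
}

#' Delta epigenetic age
#'
#' Adds `delta_age = clock_value - age` for age-estimating clocks; a
#' positive delta indicates accelerated epigenetic aging. Pace-style scores
#' pass through unchanged (delta left NA) with a warning.
#'
#' @param res clock result table with `clock_value` and `age` columns.
#' @param is_age_estimator whether the clock estimates age in years.
#'
#' @return The table with a `delta_age` column.
#' @export
delta_age <- function(res, is_age_estimator = TRUE) {
  if (!is_age_estimator) {
    warning("pace-style clock: raw values are used, no delta age formed",
            call. = FALSE)
    res$delta_age <- NA_real_
    return(res)
  }
  if (!"age" %in% names(res)) stop_mp("chronological age column is required")
  res$delta_age <- res$clock_value - res$age
  res
}

#' Replace extreme low outliers by the second-lowest value
#'
#' Values strictly below `mean - 3 * SD` (moments computed on the input)
#' are replaced by the second-lowest distinct value of the original vector,
#' a data-retention rule used instead of excluding flagged subjects. The
#' rule is idempotent. Ties: if the two lowest observations are equal, the
#' replacement is the second-lowest *distinct* original value.
#'
#' @param values numeric vector (length >= 3).
#'
#' @return The vector with low outliers replaced.
#' @export
replace_low_outliers <- function(values) {
  if (length(values) < 3) stop_mp("need at least 3 values")
  cutoff <- mean(values, na.rm = TRUE) - 3 * stats::sd(values, na.rm = TRUE)
  low <- !is.na(values) & values < cutoff
  if (!any(low)) return(values)
  distinct <- sort(unique(values[!is.na(values)]))
  if (length(distinct) < 2) return(values)
  values[low] <- distinct[2]
  values
}
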