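#' Z-score a numeric vector
#'
#' Centres to mean zero and scales to unit standard deviation using the
#' sample SD (denominator n - 1), the convention used for all per-SD odds
#' and hazard ratios in this package; scaling is computed within the cohort
#' being analysed.
#'
#' @param values numeric vector with positive variance.
#'
#' @return The z-scored vector (names kept).
#' @export
zscale <- function(values) {
  s <- stats::sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop_mp("zero variance: cannot z-score")
  (values - mean(values, na.rm = TRUE)) / s
}

is_binary <- function(x) {
  is.numeric(x) && length(unique(stats::na.omit(x))) <= 2
}

zscale_continuous <- function(predictors) {
  for (nm in names(predictors)) {
    x <- predictors[[nm]]
    if (is.numeric(x) && !is_binary(x)) predictors[[nm]] <- zscale(x)
  }
  predictors
}

risk_table <- function(est, se, p, ratio_name) {
  ci_lo <- exp(est - 1.96 * se)
  ci_hi <- exp(est + 1.96 * se)
  out <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se), ratio = exp(unname(est)),
                    ci_low = unname(ci_lo), ci_high = unname(ci_hi),
                    p = unname(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "ratio"] <- ratio_name
  out
}

#' Logistic regression with per-SD odds ratios
#'
#' Maximum-likelihood logistic fit of a binary outcome on a predictor
#' table. Continuous (non-binary) predictors are z-scored by default, so
#' odds ratios read as the change per one standard deviation's increase;
#' binary indicators are left on their natural scale. Perfect separation is
#' detected (divergent fitted probabilities) and flagged rather than
#' reported as a silently huge estimate. Model discrimination is summarised
#' by the C-statistic of the fitted probabilities.
#'
#' @param outcome binary 0/1 vector (both classes present).
#' @param predictors data.frame of predictors (same length).
#' @param z_continuous z-score continuous predictors first.
#'
#' @return Object of class `risk_model`: `coefficients` (term, estimate,
#'   se, OR, 95% CI, p), `auc`, `n_cases`, `n_controls`, `separation`.
#' @export
fit_logistic <- function(outcome, predictors, z_continuous = TRUE) {
  outcome <- as.numeric(outcome)
  if (length(unique(stats::na.omit(outcome))) != 2) {
    stop_mp("both outcome classes must be present")
  }
  predictors <- as.data.frame(predictors)
  if (z_continuous) predictors <- zscale_continuous(predictors)
  dat <- cbind(data.frame(.outcome = outcome), predictors)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.outcome ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  res <- risk_table(stats::setNames(cf[, 1], rownames(cf)), cf[, 2],
                    cf[, 4], "odds_ratio")
  structure(list(coefficients = res,
                 auc = c_statistic(stats::fitted(fit), outcome),
                 n_cases = sum(outcome == 1),
                 n_controls = sum(outcome == 0),
                 separation = sep, model = fit,
                 kind = "logistic"),
            class = "risk_model")
}

#' Cox proportional-hazards regression with per-SD hazard ratios
#'
#' Partial-likelihood maximization (`survival::coxph`, Efron tie handling)
#' of time-to-event on a predictor table; continuous predictors are
#' z-scored by default. Time is measured in years from the baseline sample
#' to clinical onset for cases and to last follow-up (censored) for
#' controls. Monotone-likelihood fits (a coefficient running to infinity)
#' are flagged.
#'
#' @param time_to_event nonnegative times in years.
#' @param event binary event indicator (at least one event).
#' @param predictors data.frame of predictors.
#' @param z_continuous z-score continuous predictors first.
#'
#' @return Object of class `risk_model` with hazard ratios and the model
#'   concordance as `auc`.
#' @export
fit_cox <- function(time_to_event, event, predictors, z_continuous = TRUE) {
  if (sum(event) < 1) stop_mp("at least one event is required")
  if (any(time_to_event < 0)) stop_mp("event times must be nonnegative")
  predictors <- as.data.frame(predictors)
  if (z_continuous) predictors <- zscale_continuous(predictors)
  dat <- cbind(data.frame(.time = time_to_event, .event = event),
               predictors)
  mono <- FALSE
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(predictors), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) mono <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  res <- risk_table(stats::setNames(cf[, "coef"], rownames(cf)),
                    cf[, "se(coef)"], cf[, "Pr(>|z|)"], "hazard_ratio")
  structure(list(coefficients = res,
                 auc = unname(fit$concordance["concordance"]),
                 n_cases = sum(event == 1), n_controls = sum(event == 0),
                 separation = mono, model = fit, kind = "cox"),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("%s model: %d cases / %d controls, C-statistic %.3f%s\n",
              if (x$kind == "cox") "Cox" else "Logistic",
              x$n_cases, x$n_controls, x$auc,
              if (x$separation) " [separation / monotone likelihood]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' C-statistic (ROC area under the curve)
#'
#' The probability that a randomly chosen case receives a higher score than
#' a randomly chosen control, with ties credited one half; computed from
#' midranks, so it equals exhaustive pair counting and is invariant under
#' strictly monotone score transforms.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (1 = case).
#'
#' @return Scalar in \[0, 1\].
#' @export
c_statistic <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_mp("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (1 = case).
#'
#' @return data.frame of `threshold`, `fpr`, `tpr` (thresholds descending;
#'   a point is "positive" when score >= threshold).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!any(labels == 1) || !any(labels == 0)) {
    stop_mp("both classes must be present")
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(threshold = th,
             fpr = vapply(th, function(t) mean(scores[labels == 0] >= t),
                          numeric(1)),
             tpr = vapply(th, function(t) mean(scores[labels == 1] >= t),
                          numeric(1)))
}

#' Per-subject telomere-attrition slopes
#'
#' Ordinary least-squares slope of relative leukocyte telomere length (RTL)
#' on age at sampling, fitted separately per subject; subjects with fewer
#' than two visits get a missing slope with a warning.
#'
#' @param records data.frame with `subject_id`, `age`, `rtl`.
#'
#' @return Named numeric vector of slopes (RTL units per year).
#' @export
rtl_slope <- function(records) {
  stopifnot(all(c("subject_id", "age", "rtl") %in% names(records)))
  ids <- unique(records$subject_id)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  short <- character(0)
  for (id in ids) {
    sub <- records[records$subject_id == id, ]
    if (nrow(sub) < 2) { short <- c(short, id); next }
    out[id] <- stats::coef(stats::lm(rtl ~ age, data = sub))[["age"]]
  }
  if (length(short)) {
    warning(length(short), " subject(s) with < 2 visits: slope set missing",
            call. = FALSE)
  }
  out
}

#' External-cohort validation of a methylation panel
#'
#' Computes the signed-sum panel score on an external cohort, fits adjusted
#' logistic models (APOE e4, sex, granulocyte proportion, chronological
#' age) with and without the z-scored panel score, and reports per-SD odds
#' ratios and AUCs for both, plus a per-CpG univariate logistic replication
#' with direction-concordance counting (a panel CpG replicates in direction
#' when the sign of its adjusted log-odds coefficient matches its panel
#' sign).
#'
#' @param panel a [select_panel()] panel.
#' @param beta external CpG x sample beta matrix (must contain the panel
#'   probes).
#' @param samples external sample sheet with `sample_id`, `ad`, `sex`,
#'   `age`, `apoe_e4`, `granulocyte`.
#' @param weighted use the effect-size-weighted panel score.
#'
#' @return List: `score_model` and `covariate_model` ([fit_logistic()]
#'   results), `auc_with_score`, `auc_covariates_only`, `per_cpg`
#'   (probe_id, estimate, odds_ratio, p, panel_sign, concordant),
#'   `n_concordant`, `score` (the per-sample panel score).
#' @export
validate_external <- function(panel, beta, samples, weighted = FALSE) {
  need <- c("sample_id", "ad", "sex", "age", "apoe_e4", "granulocyte")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    stop_mp("sample sheet lacks column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  stopifnot(identical(colnames(beta), samples$sample_id))
  score <- panel_score(beta, panel, weighted = weighted)
  covars <- data.frame(apoe_e4 = samples$apoe_e4,
                       sex = as.integer(samples$sex == "M"),
                       granulocyte = samples$granulocyte,
                       age = samples$age)
  cov_model <- fit_logistic(samples$ad, covars)
  score_model <- fit_logistic(samples$ad,
                              cbind(panel_score = as.numeric(score), covars))

  per <- lapply(seq_len(nrow(panel)), function(i) {
    pid <- panel$probe_id[i]
    b <- beta[pid, ]
    fit <- fit_logistic(samples$ad, cbind(beta = as.numeric(b), covars))
    row <- fit$coefficients[fit$coefficients$term == "beta", ]
    data.frame(probe_id = pid, estimate = row$estimate,
               odds_ratio = row$odds_ratio, p = row$p,
               panel_sign = panel$sign[i],
               concordant = sign(row$estimate) == panel$sign[i],
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(score_model = score_model, covariate_model = cov_model,
       auc_with_score = score_model$auc,
       auc_covariates_only = cov_model$auc,
       per_cpg = per,
       n_concordant = if (is.null(per)) 0L else sum(per$concordant),
       score = score)
}
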