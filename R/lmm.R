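#' Specify the longitudinal mixed model
#'
#' Describes the fixed and random structure of the two-level nested
#' random-intercept Gaussian model used throughout:
#' `response ~ AD + time + AD:time + APOE e4 + smoking + granulocyte +
#' (1 | pair) + (1 | subject)`, with subjects nested within matched pairs
#' (subject IDs are unique, so crossed coding is equivalent to explicit
#' nesting). Time is measured either in years to/after clinical onset or as
#' chronological age.
#'
#' @param response name of the response column in the data.
#' @param ad,time,interaction,apoe,smoking,granulocyte logical toggles for
#'   the fixed terms. The interaction requires both main effects.
#' @param time_scale "time_to_onset" or "age"; names the time column used.
#' @param p_method "wald_z" (normal reference, default) or "t_residual"
#'   (t with residual degrees of freedom).
#'
#' @return An object of class `lmm_spec`.
#' @export
lmm_spec <- function(response = "y", ad = TRUE, time = TRUE,
                     interaction = TRUE, apoe = TRUE, smoking = TRUE,
                     granulocyte = TRUE,
                     time_scale = c("time_to_onset", "age"),
                     p_method = c("wald_z", "t_residual")) {
  time_scale <- match.arg(time_scale)
  p_method <- match.arg(p_method)
  if (interaction && !(ad && time)) {
    stop_mp("the AD-by-time interaction requires both main effects")
  }
  structure(list(response = response, ad = ad, time = time,
                 interaction = interaction, apoe = apoe, smoking = smoking,
                 granulocyte = granulocyte, time_scale = time_scale,
                 p_method = p_method),
            class = "lmm_spec")
}

lmm_fixed_terms <- function(spec) {
  terms <- character(0)
  if (spec$ad) terms <- c(terms, "ad")
  if (spec$time) terms <- c(terms, spec$time_scale)
  if (spec$apoe) terms <- c(terms, "apoe_e4")
  if (spec$smoking) terms <- c(terms, "smoker")
  if (spec$granulocyte) terms <- c(terms, "granulocyte")
  if (spec$interaction) terms <- c(terms, paste0("ad:", spec$time_scale))
  terms
}

lmm_formula <- function(spec) {
  rhs <- paste(c(lmm_fixed_terms(spec), "(1 | pair_id)", "(1 | subject_id)"),
               collapse = " + ")
  stats::as.formula(paste(spec$response, "~", rhs))
}

lmm_design_matrix <- function(spec, data) {
  rhs <- paste(c("1", lmm_fixed_terms(spec)), collapse = " + ")
  stats::model.matrix(stats::as.formula(paste("~", rhs)), data = data)
}

wald_table <- function(est, se, df, p_method) {
  z <- est / se
  p <- if (p_method == "t_residual") {
    2 * stats::pt(-abs(z), df = df)
  } else {
    2 * stats::pnorm(-abs(z))
  }
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             statistic = unname(z), p = pmin(pmax(unname(p), 1e-300), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the longitudinal nested random-intercept model
#'
#' REML estimation via `lme4::lmer` of the model described by an
#' [lmm_spec()]; fixed-effect p-values by Wald test (normal reference by
#' default). Non-convergence is flagged, not raised; a singular fit pins
#' the offending variance component at zero and sets the `singular` flag.
#' When `varcomp` supplies known variance components
#' `(pair, subject, residual)`, the model is instead solved as generalized
#' least squares with the implied marginal covariance (the exact solution
#' the REML fit targets), which is also the `varcomp = c(0, 0, s2)` route
#' to an ordinary least-squares fit.
#'
#' @param data long-format data.frame with the response plus `ad`,
#'   `time_to_onset` (or `age`), `apoe_e4`, `smoker`, `granulocyte`,
#'   `subject_id`, `pair_id` as required by the spec.
#' @param spec an [lmm_spec()].
#' @param varcomp optional named numeric vector `c(pair=, subject=,
#'   residual=)` of known variance components for the GLS route.
#'
#' @return An object of class `lmm_fit`: `coefficients` (term, estimate,
#'   se, statistic, p), `varcomp`, `converged`, `singular`, `n_obs`.
#' @export
fit_lmm <- function(data, spec = lmm_spec(), varcomp = NULL) {
  resp <- data[[spec$response]]
  if (is.null(resp) || !is.numeric(resp)) {
    stop_mp("response column '", spec$response, "' must be numeric")
  }
  if (length(unique(data$subject_id[data$ad == 1])) < 2 ||
      length(unique(data$subject_id[data$ad == 0])) < 2) {
    stop_mp("need at least 2 subjects per group")
  }

  if (!is.null(varcomp)) {
    return(fit_lmm_gls(data, spec, varcomp))
  }

  conv <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(lmm_formula(spec), data = data, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w))) conv <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  lmm_fit_from_lmer(fit, spec, converged = conv)
}

lmm_fit_from_lmer <- function(fit, spec, converged = TRUE) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n <- stats::nobs(fit)
  df <- n - length(est)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- c(pair = vc$vcov[vc$grp == "pair_id"][1],
             subject = vc$vcov[vc$grp == "subject_id"][1],
             residual = vc$vcov[vc$grp == "Residual"][1])
  structure(list(coefficients = wald_table(est, se, df, spec$p_method),
                 varcomp = vcomp,
                 converged = converged,
                 singular = lme4::isSingular(fit),
                 n_obs = n, spec = spec, model = fit),
            class = "lmm_fit")
}

# GLS with a known two-level nested covariance; exact, no iteration
fit_lmm_gls <- function(data, spec, varcomp) {
  X <- lmm_design_matrix(spec, data)
  y <- data[[spec$response]]
  Zs <- stats::model.matrix(~ 0 + factor(data$subject_id))
  Zp <- stats::model.matrix(~ 0 + factor(data$pair_id))
  V <- diag(varcomp[["residual"]], nrow(X)) +
    varcomp[["subject"]] * tcrossprod(Zs) +
    varcomp[["pair"]] * tcrossprod(Zp)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  cov_b <- solve(XtVi %*% X)
  est <- drop(cov_b %*% (XtVi %*% y))
  names(est) <- colnames(X)
  se <- sqrt(diag(cov_b))
  structure(list(coefficients = wald_table(est, se,
                                           nrow(X) - ncol(X), spec$p_method),
                 varcomp = c(pair = varcomp[["pair"]],
                             subject = varcomp[["subject"]],
                             residual = varcomp[["residual"]]),
                 converged = TRUE, singular = FALSE,
                 n_obs = nrow(X), spec = spec, model = NULL),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Nested random-intercept LMM (%d obs)%s%s\n", x$n_obs,
              if (!x$converged) " [did not converge]" else "",
              if (x$singular) " [singular fit]" else ""))
  print(x$coefficients, digits = 4)
  cat(sprintf("Variance components: pair %.4g, subject %.4g, residual %.4g\n",
              x$varcomp["pair"], x$varcomp["subject"],
              x$varcomp["residual"]))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' CpG-wise longitudinal mixed-model scan
#'
#' Fits the nested random-intercept model of [lmm_spec()] to every probe of
#' a complete beta matrix, one probe at a time, reusing one compiled model
#' structure via `lme4::refit` for speed. For each probe the AD main
#' effect, the time and AD-by-time terms, and the fitted case-control
#' difference evaluated at the earliest and latest observed times (the
#' quantity used by the crossover exclusion rule) are reported.
#' Zero-variance probes and per-probe failures are recorded and skipped;
#' the scan continues.
#'
#' @param m complete CpG x sample beta matrix (no missing values).
#' @param sheet sample sheet with columns matching the spec (see
#'   [fit_lmm()]); `granulocyte` must be present when the spec includes it.
#' @param spec an [lmm_spec()] (its `response` field is ignored).
#' @param verbose log progress every `chunk` probes.
#' @param chunk progress interval.
#'
#' @return A data.frame with one row per probe: `probe_id`, `estimate`,
#'   `se`, `p`, `q` (Benjamini-Hochberg), `estimate_time`, `p_time`,
#'   `estimate_interaction`, `p_interaction`, `diff_at_tmin`,
#'   `diff_at_tmax`, `converged`, `singular`, `note`.
#' @export
ewas_scan <- function(m, sheet, spec = lmm_spec(), verbose = FALSE,
                      chunk = 1000) {
  assert_beta_matrix(m)
  if (anyNA(m)) stop_mp("the scan requires a complete (imputed) matrix")
  stopifnot(identical(colnames(m), sheet$sample_id))
  spec$response <- "y"
  tcol <- spec$time_scale
  tmin <- min(sheet[[tcol]]); tmax <- max(sheet[[tcol]])

  dat <- sheet
  dat$y <- m[1, ]
  template <- suppressWarnings(suppressMessages(
    lme4::lmer(lmm_formula(spec), data = dat, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  terms_all <- names(lme4::fixef(template))
  i_ad <- match("ad", terms_all)
  i_time <- match(tcol, terms_all)
  i_int <- match(paste0("ad:", tcol), terms_all)
  if (is.na(i_ad)) stop_mp("the scan spec must include the AD term")

  n <- nrow(m)
  out <- data.frame(probe_id = rownames(m), estimate = NA_real_,
                    se = NA_real_, p = NA_real_, q = NA_real_,
                    estimate_time = NA_real_, p_time = NA_real_,
                    estimate_interaction = NA_real_,
                    p_interaction = NA_real_,
                    diff_at_tmin = NA_real_, diff_at_tmax = NA_real_,
                    converged = NA, singular = NA, note = "",
                    stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    y <- m[j, ]
    if (stats::sd(y) < 1e-10) {
      out$note[j] <- "zero variance"
      next
    }
    fit <- tryCatch(suppressWarnings(suppressMessages(
      lme4::refit(template, newresp = y))), error = function(e) NULL)
    if (is.null(fit)) {
      out$note[j] <- "fit failed"
      next
    }
    est <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    se <- sqrt(diag(vc))
    zp <- function(i) 2 * stats::pnorm(-abs(est[i] / se[i]))
    out$estimate[j] <- est[i_ad]
    out$se[j] <- se[i_ad]
    out$p[j] <- max(zp(i_ad), 1e-300)
    if (!is.na(i_time)) {
      out$estimate_time[j] <- est[i_time]
      out$p_time[j] <- zp(i_time)
    }
    if (!is.na(i_int)) {
      out$estimate_interaction[j] <- est[i_int]
      out$p_interaction[j] <- zp(i_int)
      out$diff_at_tmin[j] <- est[i_ad] + est[i_int] * tmin
      out$diff_at_tmax[j] <- est[i_ad] + est[i_int] * tmax
    } else {
      out$diff_at_tmin[j] <- out$diff_at_tmax[j] <- est[i_ad]
    }
    out$converged[j] <- TRUE
    out$singular[j] <- lme4::isSingular(fit)
    if (verbose && j %% chunk == 0) {
      message("scanned ", j, " / ", n, " probes")
    }
  }
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  attr(out, "time_range") <- c(tmin = tmin, tmax = tmax)
  out
}

#' Genomic inflation factor
#'
#' Lambda is the median of the one-degree-of-freedom chi-square quantiles
#' implied by the p-values, divided by the null chi-square median
#' (0.4549364): 1.0 indicates no inflation of the test statistics.
#'
#' @param pvals p-values in (0, 1].
#'
#' @return Scalar lambda.
#' @export
genomic_lambda <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop_mp("p-values must lie in (0, 1]")
  }
  if (length(pvals) < 100) {
    warning("genomic lambda is unstable below 100 p-values", call. = FALSE)
  }
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1 (`stats::p.adjust(method = "BH")`).
#'
#' @param pvals p-values in \[0, 1\].
#'
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_mp("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}
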