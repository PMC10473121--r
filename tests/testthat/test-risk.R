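test_that("z-scoring uses the sample-SD convention and is affine-invariant", {
  z <- zscale(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))         # sample SD (n - 1), not population
  expect_equal(zscale(z), z, tolerance = 1e-12)
  expect_equal(zscale(5 + 2 * c(1, 2, 3)), z, tolerance = 1e-12)
  expect_error(zscale(rep(1, 5)), "zero variance")
})

test_that("logistic fits reproduce the closed-form 2x2 odds ratio", {
  # cross-tab: 112 exposed cases, 34 unexposed cases, 76 exposed controls,
  # 248 unexposed controls
  outcome <- c(rep(1, 112 + 34), rep(0, 76 + 248))
  exposed <- c(rep(1, 112), rep(0, 34), rep(1, 76), rep(0, 248))
  fit <- fit_logistic(outcome, data.frame(exposed = exposed))
  or <- fit$coefficients$odds_ratio[fit$coefficients$term == "exposed"]
  expect_equal(or, (112 * 248) / (34 * 76), tolerance = 1e-6)
  expect_equal(fit$n_cases, 146)
  expect_equal(fit$n_controls, 324)
  expect_true(fit$auc > 0.5)
})

test_that("per-SD odds ratios are invariant to predictor rescaling", {
  set.seed(41)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(0.8 * x))
  f1 <- fit_logistic(y, data.frame(x = x))
  f2 <- fit_logistic(y, data.frame(x = 1000 * x + 7))
  expect_equal(f1$coefficients$odds_ratio, f2$coefficients$odds_ratio,
               tolerance = 1e-10)
  # null predictor: OR near 1
  set.seed(42)
  f0 <- fit_logistic(rbinom(2000, 1, 0.5), data.frame(x = rnorm(2000)))
  expect_equal(f0$coefficients$odds_ratio[2], 1, tolerance = 0.15)
  ci <- f0$coefficients
  expect_true(all(ci$ci_low <= ci$odds_ratio & ci$odds_ratio <= ci$ci_high))
  expect_error(fit_logistic(rep(1, 10), data.frame(x = rnorm(10))),
               "both outcome classes")
})

test_that("perfect separation is detected, not silently diverged", {
  y <- c(rep(0, 10), rep(1, 10))
  x <- c(rnorm(10, -5), rnorm(10, 5))
  fit <- fit_logistic(y, data.frame(x = x))
  expect_true(fit$separation)
})

test_that("Cox fits match the brute-force partial likelihood", {
  # 4-subject no-ties toy
  time <- c(2, 5, 7, 9)
  event <- c(1, 1, 1, 0)
  x <- c(1.2, -0.5, 0.3, -1)
  fit <- fit_cox(time, event, data.frame(x = x), z_continuous = FALSE)
  hr <- fit$coefficients$hazard_ratio[1]
  expect_equal(hr, cox_brute_hr(time, event, x), tolerance = 1e-6)
  # time-scale invariance
  fit2 <- fit_cox(time * 3.7, event, data.frame(x = x),
                  z_continuous = FALSE)
  expect_equal(fit2$coefficients$hazard_ratio, fit$coefficients$hazard_ratio,
               tolerance = 1e-8)
  expect_error(fit_cox(time, rep(0, 4), data.frame(x = x)), "one event")
  expect_error(fit_cox(c(-1, 2, 3, 4), event, data.frame(x = x)),
               "nonnegative")
})

test_that("a null covariate has hazard ratio near one", {
  set.seed(43)
  n <- 600
  time <- rexp(n)
  event <- rbinom(n, 1, 0.7)
  fit <- fit_cox(time, event, data.frame(x = rnorm(n)))
  expect_equal(fit$coefficients$hazard_ratio[1], 1, tolerance = 0.15)
})

test_that("the C-statistic equals exhaustive pair counting", {
  expect_equal(c_statistic(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(c_statistic(rep(3, 8), rep(c(0, 1), 4)), 0.5)
  # value frozen from the exhaustive pair-enumeration oracle
  expect_equal(cstat_pairs(c(0.1, 0.4, 0.35, 0.8), c(0, 1, 0, 1)), 1)
  expect_equal(c_statistic(c(0.1, 0.4, 0.35, 0.8), c(0, 1, 0, 1)), 1)
  expect_equal(c_statistic(c(0.1, 0.4, 0.35, 0.8), c(1, 0, 0, 1)), 0.5)
  set.seed(44)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    s <- sample(1:6, n, replace = TRUE)  # forces ties
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(c_statistic(s, l), cstat_pairs(s, l))
    # invariance under strictly monotone transforms
    expect_equal(c_statistic(exp(s), l), c_statistic(s, l))
  }
  expect_error(c_statistic(1:4, rep(1, 4)), "both classes")
})

test_that("the C-statistic matches an established ROC implementation", {
  set.seed(45)
  s <- rnorm(80)
  l <- rbinom(80, 1, plogis(s))
  expect_equal(c_statistic(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))))
  rc <- roc_curve(s, l)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_true(all(diff(rc$tpr) >= 0) && all(diff(rc$fpr) >= 0))
})

test_that("telomere slopes are per-subject least squares", {
  rec <- data.frame(subject_id = rep(c("a", "b", "c", "d"), c(3, 3, 2, 1)),
                    age = c(60, 65, 70, 60, 65, 70, 60, 70, 66),
                    rtl = c(2 - 0.01 * c(60, 65, 70), rep(1.3, 3),
                            1.0, 0.8, 1.1))
  expect_warning(sl <- rtl_slope(rec), "< 2 visits")
  expect_equal(unname(sl["a"]), -0.01, tolerance = 1e-12)
  expect_equal(unname(sl["b"]), 0, tolerance = 1e-12)
  expect_equal(unname(sl["c"]), (0.8 - 1.0) / 10)
  expect_true(is.na(sl["d"]))
})

test_that("external validation finds planted signal and nulls alike", {
  cfg <- cohort_config(n_cpgs = 400, n_pairs = 10,
                       n_stable_effect_cpgs = 12, n_interaction_cpgs = 0,
                       n_crossover_cpgs = 0, n_aging_cpgs = 0,
                       n_clock_cpgs = 0, effect_size_delta_beta = 0.08,
                       seed = 46)
  coh <- generate_cohort(cfg)
  truth <- coh$truth
  stable <- truth$class == "stable"
  panel <- structure(data.frame(probe_id = truth$cpg_id[stable],
                                sign = sign(truth$true_delta_beta[stable]),
                                weight = truth$true_delta_beta[stable]),
                     class = c("panel_definition", "data.frame"))

  run_validation <- function(attenuation, seed) {
    ext <- generate_external_cohort(cfg, truth, n_controls = 250,
                                    n_cases = 250,
                                    attenuation = attenuation, seed = seed)
    props <- estimate_proportions(ext$beta, truth$reference)
    ext$samples$granulocyte <- props$granulocyte
    validate_external(panel, ext$beta, ext$samples)
  }

  null_res <- run_validation(0, 47)
  or0 <- null_res$score_model$coefficients
  or0 <- or0$odds_ratio[or0$term == "panel_score"]
  expect_equal(or0, 1, tolerance = 0.25)
  expect_lt(abs(null_res$auc_with_score - null_res$auc_covariates_only),
            0.05)

  full_res <- run_validation(1, 48)
  expect_gt(full_res$auc_with_score, full_res$auc_covariates_only)
  orf <- full_res$score_model$coefficients
  expect_gt(orf$odds_ratio[orf$term == "panel_score"], 1.5)
  # all planted directions preserved at full effect size
  expect_equal(full_res$n_concordant, sum(stable))

  bad <- generate_external_cohort(cfg, truth, n_controls = 20, n_cases = 20,
                                  seed = 49)
  expect_error(validate_external(panel, bad$beta, bad$samples),
               "granulocyte")
})
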