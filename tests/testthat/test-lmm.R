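# a small balanced long-format dataset for LMM unit tests
toy_long <- function(n_pairs = 10, visits = c(-10, -4, 2), seed = 1,
                     gen = function(d) 0.5 + 0.05 * d$ad) {
  set.seed(seed)
  d <- expand.grid(visit = seq_along(visits), ad = c(1, 0),
                   pair = seq_len(n_pairs))
  d$pair_id <- sprintf("p%02d", d$pair)
  d$subject_id <- sprintf("%s_%d", d$pair_id, d$ad)
  d$time_to_onset <- visits[d$visit]
  d$apoe_e4 <- rbinom(n_pairs * 2, 1, 0.4)[as.integer(factor(d$subject_id))]
  d$smoker <- rbinom(n_pairs * 2, 1, 0.3)[as.integer(factor(d$subject_id))]
  d$granulocyte <- runif(nrow(d), 0.5, 0.7)
  d$y <- gen(d)
  d
}

test_that("a noise-free fixed-effect structure is interpolated exactly", {
  d <- toy_long(gen = function(d) 0.5 + 0.05 * d$ad)
  spec <- lmm_spec(time = FALSE, interaction = FALSE, apoe = FALSE,
                   smoking = FALSE, granulocyte = FALSE)
  fit <- fit_lmm(d, spec)
  est <- coef(fit)
  expect_equal(unname(est["(Intercept)"]), 0.5, tolerance = 1e-7)
  expect_equal(unname(est["ad"]), 0.05, tolerance = 1e-7)
})

test_that("known-variance fits match the closed-form GLS oracle", {
  d <- toy_long(n_pairs = 2, visits = c(-8, 3), seed = 2,
                gen = function(d) {
                  0.4 + 0.06 * d$ad + 0.002 * d$time_to_onset +
                    rnorm(nrow(d), 0, 0.05)
                })
  spec <- lmm_spec(interaction = FALSE, apoe = FALSE, smoking = FALSE,
                   granulocyte = FALSE)
  vc <- c(pair = 0.02, subject = 0.01, residual = 0.05^2)
  fit <- fit_lmm(d, spec, varcomp = vc)
  X <- cbind(1, d$ad, d$time_to_onset)
  oracle <- gls_oracle(X, d$y, d$subject_id, d$pair_id,
                       vc["pair"], vc["subject"], vc["residual"])
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-6)
})

test_that("zero variance components reduce the fit to ordinary least squares", {
  d <- toy_long(seed = 3, gen = function(d) {
    0.3 + 0.04 * d$ad + rnorm(nrow(d), 0, 0.03)
  })
  spec <- lmm_spec(time = FALSE, interaction = FALSE, apoe = FALSE,
                   smoking = FALSE, granulocyte = FALSE)
  fit <- fit_lmm(d, spec, varcomp = c(pair = 0, subject = 0, residual = 1))
  ols <- coef(lm(y ~ ad, data = d))
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-8)
})

test_that("REML fits estimate planted fixed effects and flag singularity", {
  d <- toy_long(n_pairs = 40, seed = 4, gen = function(d) {
    subj <- as.integer(factor(d$subject_id))
    0.4 + 0.08 * d$ad + rnorm(80, 0, 0.05)[subj] +
      rnorm(nrow(d), 0, 0.05)
  })
  fit <- fit_lmm(d, lmm_spec())
  expect_s3_class(fit, "lmm_fit")
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "ad"], 0.08, tolerance = 0.04)
  expect_true(all(cf$se > 0))
  expect_true(all(cf$p > 0 & cf$p <= 1))
  expect_true(all(fit$varcomp >= 0))
  expect_error(fit_lmm(d[d$pair_id == "p01", ], lmm_spec()),
               "2 subjects")
  expect_error(lmm_spec(ad = FALSE, interaction = TRUE), "both main")
})

test_that("the scan recovers planted effects and flags crossovers", {
  cfg <- cohort_config(n_cpgs = 60, n_pairs = 40,
                       n_stable_effect_cpgs = 5, n_interaction_cpgs = 0,
                       n_crossover_cpgs = 5, n_aging_cpgs = 0,
                       n_clock_cpgs = 0, effect_size_delta_beta = 0.08,
                       seed = 12)
  coh <- generate_cohort(cfg)
  sheet <- coh$samples
  props <- coh$truth$cell_proportions
  sheet$granulocyte <- props[sheet$sample_id, "granulocyte"]
  res <- ewas_scan(coh$beta, sheet, lmm_spec())
  stable <- coh$truth$class == "stable"
  signed <- res$estimate[stable] * sign(coh$truth$true_delta_beta[stable])
  expect_lt(abs(mean(signed) - 0.08), 0.02)
  cross <- coh$truth$class == "crossover"
  expect_true(all(sign(res$diff_at_tmin[cross]) !=
                    sign(res$diff_at_tmax[cross])))
  # zero-variance probes are skipped, not fatal
  m2 <- coh$beta
  m2[1, ] <- 0.5
  res2 <- ewas_scan(m2, sheet, lmm_spec())
  expect_equal(res2$note[1], "zero variance")
  expect_true(is.na(res2$p[1]))
})

test_that("genomic lambda behaves at its landmarks", {
  expect_warning(l <- genomic_lambda(rep(0.5, 50)), "unstable")
  expect_equal(l, 1.0)
  set.seed(13)
  z <- rnorm(20000)
  p1 <- 2 * pnorm(-abs(z))
  p2 <- 2 * pnorm(-abs(2 * z))   # doubled statistics
  l1 <- genomic_lambda(p1)
  l2 <- genomic_lambda(p2)
  expect_equal(l1, 1.0, tolerance = 0.05)
  expect_equal(l2 / l1, 4, tolerance = 0.2)  # chi-square scales as z^2
  expect_error(genomic_lambda(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("panel selection applies the composite rule", {
  res <- data.frame(
    probe_id = c("cg1", "cg2", "cg3", "cg4"),
    estimate = c(0.06, 0.04, -0.06, -0.07),
    p = c(5e-4, 5e-4, 5e-4, 0.01),
    diff_at_tmin = c(0.05, 0.03, -0.04, -0.06),
    diff_at_tmax = c(0.07, 0.05, 0.02, -0.08))
  panel <- select_panel(res)
  # cg1 selected (+1); cg2 under effect threshold; cg3 crossover; cg4 p too big
  expect_equal(panel$probe_id, "cg1")
  expect_equal(panel$sign, 1)
  expect_equal(panel$weight, 0.06)
  expect_warning(empty <- select_panel(res, p_thresh = 1e-10), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("the signed-sum score is linear and order-invariant", {
  m <- toy_beta(2, 1, values = c(0.6, 0.4))
  panel <- structure(data.frame(probe_id = rownames(m), sign = c(1, -1),
                                weight = c(1, -1)),
                     class = c("panel_definition", "data.frame"),
                     p_thresh = 0.001, effect_thresh = 0.05)
  expect_equal(unname(panel_score(m, panel)), 0.2)
  expect_equal(unname(panel_score(m * 0, panel)), 0)
  expect_equal(panel_score(m, panel, weighted = TRUE),
               panel_score(m, panel))
  m5 <- toy_beta(5, 4)
  pan5 <- structure(data.frame(probe_id = rownames(m5),
                               sign = c(1, -1, 1, 1, -1),
                               weight = runif(5)),
                    class = c("panel_definition", "data.frame"))
  perm <- c(4, 2, 5, 1, 3)
  pan_perm <- pan5[perm, ]
  expect_equal(panel_score(m5, pan5), panel_score(m5, pan_perm))
  expect_equal(panel_score(2 / 3 * m5, pan5), 2 / 3 * panel_score(m5, pan5))
  expect_error(panel_score(m5[1:3, ], pan5), "absent")
})
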