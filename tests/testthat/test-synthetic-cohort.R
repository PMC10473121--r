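test_that("reference panel has the promised geometry", {
  ref <- generate_reference_panel(600, 6, seed = 1)
  expect_equal(dim(ref), c(600, 6))
  expect_true(all(ref >= 0 & ref <= 1))
  disc <- attr(ref, "discriminating")
  expect_gt(length(disc), 0)
  spreads <- apply(ref[disc, , drop = FALSE], 1, function(r) diff(range(r)))
  expect_true(all(spreads >= 0.3))
  # full column rank, verified by an independent rank computation
  expect_equal(qr(ref)$rank, 6)

  tiny <- generate_reference_panel(2, 2, seed = 1)
  expect_true(all(apply(tiny, 1, function(r) diff(range(r))) >= 0.3))
  expect_error(generate_reference_panel(10, 1), "2 cell types")
})

test_that("cohort generation is deterministic and seed-sensitive", {
  cfg <- cohort_config(n_cpgs = 200, n_pairs = 5, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$samples, b$samples)
  c2 <- generate_cohort(cohort_config(n_cpgs = 200, n_pairs = 5, seed = 43))
  expect_false(identical(a$beta, c2$beta))
})

test_that("matched-pair bookkeeping holds", {
  coh <- generate_cohort(cohort_config(n_cpgs = 100, n_pairs = 30,
                                       seed = 2))
  sheet <- coh$samples
  for (p in unique(sheet$pair_id)) {
    sub <- sheet[sheet$pair_id == p, ]
    case <- sub[sub$ad == 1, ]
    ctrl <- sub[sub$ad == 0, ]
    expect_equal(length(unique(case$subject_id)), 1)
    expect_equal(length(unique(ctrl$subject_id)), 1)
    expect_equal(unique(case$sex), unique(ctrl$sex))
    # controls inherit the case's onset, ages match within a year
    expect_equal(unique(case$onset_age), unique(ctrl$onset_age))
    expect_lte(abs(min(case$age) - min(ctrl$age)), 1)
  }
  expect_true(all(sheet$time_to_onset >= -16 & sheet$time_to_onset <= 7))
})

test_that("beta values, cell proportions and missingness behave", {
  cfg <- cohort_config(n_cpgs = 1000, n_pairs = 20, missing_rate = 0.03,
                       seed = 3)
  coh <- generate_cohort(cfg)
  expect_gte(length(coh$beta), 1e5)
  expect_true(all(coh$beta >= 0 & coh$beta <= 1, na.rm = TRUE))
  rate <- mean(is.na(coh$beta))
  expect_lt(abs(rate - 0.03), 0.01)
  expect_equal(unname(rowSums(coh$truth$cell_proportions)),
               rep(1, nrow(coh$truth$cell_proportions)), tolerance = 1e-9)
  expect_true(all(table(coh$truth$class[coh$truth$class != "null"]) > 0))
})

test_that("a null configuration carries no case-control signal", {
  cfg <- cohort_config(n_cpgs = 300, n_pairs = 200,
                       n_stable_effect_cpgs = 0, n_interaction_cpgs = 0,
                       n_crossover_cpgs = 0, n_aging_cpgs = 0,
                       n_clock_cpgs = 0, seed = 4)
  coh <- generate_cohort(cfg)
  case <- coh$samples$ad == 1
  diffs <- rowMeans(coh$beta[, case]) - rowMeans(coh$beta[, !case])
  expect_lt(abs(mean(diffs)), 0.005)
  # per-CpG differences are centred noise
  expect_lt(abs(mean(diffs > 0) - 0.5), 0.1)
})

test_that("planted stable effects are recovered at their nominal size", {
  cfg <- cohort_config(n_cpgs = 300, n_pairs = 100,
                       n_stable_effect_cpgs = 20, n_interaction_cpgs = 0,
                       n_crossover_cpgs = 0, n_aging_cpgs = 0,
                       n_clock_cpgs = 0, effect_size_delta_beta = 0.08,
                       seed = 5)
  coh <- generate_cohort(cfg)
  stable <- coh$truth$class == "stable"
  case <- coh$samples$ad == 1
  diffs <- rowMeans(coh$beta[stable, case]) -
    rowMeans(coh$beta[stable, !case])
  signed <- diffs * sign(coh$truth$true_delta_beta[stable])
  expect_lt(abs(mean(signed) - 0.08), 0.01)
})

test_that("crossover CpGs flip direction at onset by construction", {
  cfg <- cohort_config(n_cpgs = 200, n_pairs = 60,
                       n_stable_effect_cpgs = 0, n_interaction_cpgs = 0,
                       n_crossover_cpgs = 10, n_aging_cpgs = 0,
                       n_clock_cpgs = 0, effect_size_delta_beta = 0.08,
                       seed = 6)
  coh <- generate_cohort(cfg)
  cross <- which(coh$truth$class == "crossover")
  pre <- coh$samples$time_to_onset < 0
  case <- coh$samples$ad == 1
  d_pre <- rowMeans(coh$beta[cross, case & pre]) -
    rowMeans(coh$beta[cross, !case & pre])
  d_post <- rowMeans(coh$beta[cross, case & !pre]) -
    rowMeans(coh$beta[cross, !case & !pre])
  expect_true(all(sign(d_pre) != sign(d_post)))
})

test_that("the bundled toy clock tracks chronological age as in blood data", {
  coh <- generate_cohort(cohort_config(seed = 1))
  res <- compute_clock(coh$beta, coh$truth$toy_clock,
                       samples = coh$samples)
  r <- cor(res$clock_value, res$age)
  expect_gte(r, 0.70)
  expect_lte(r, 0.80)
})

test_that("pairs flagged as lacking post-onset samples have none", {
  cfg <- tiny_cfg(50, 10, seed = 7, n_pairs_no_post = 2)
  coh <- generate_cohort(cfg)
  flagged <- coh$samples$pair_id %in% c("p001", "p002")
  expect_true(all(coh$samples$time_to_onset[flagged] < 0))
})

test_that("external cohort matches the requested demographic shift", {
  cfg <- cohort_config(n_cpgs = 300, n_pairs = 10, seed = 8)
  coh <- generate_cohort(cfg)
  ext <- generate_external_cohort(cfg, coh$truth, n_controls = 324,
                                  n_cases = 146, seed = 9)
  expect_equal(nrow(ext$samples), 470)
  expect_equal(anyDuplicated(ext$samples$subject_id), 0L)
  case_e4 <- mean(ext$samples$apoe_e4[ext$samples$ad == 1])
  ctrl_e4 <- mean(ext$samples$apoe_e4[ext$samples$ad == 0])
  # within ~3 binomial SDs of the configured 0.77 / 0.23
  expect_lt(abs(case_e4 - 0.77), 3 * sqrt(0.77 * 0.23 / 146))
  expect_lt(abs(ctrl_e4 - 0.23), 3 * sqrt(0.23 * 0.77 / 324))
  expect_identical(rownames(ext$beta), coh$truth$cpg_id)

  other <- generate_cohort(cohort_config(n_cpgs = 299, n_pairs = 10,
                                         seed = 8))
  expect_error(generate_external_cohort(cfg, other$truth), "alignment")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_pairs = -1), "non-negative")
  expect_error(cohort_config(cell_mean_proportions = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(cohort_config(effect_size_delta_beta = 1.2), "\\(0, 1\\)")
  expect_error(cohort_config(visit_schedule = c(-20, 0)), "\\[-16, 7\\]")
  expect_error(cohort_config(n_cpgs = 10, n_stable_effect_cpgs = 20),
               "exceed")
})
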