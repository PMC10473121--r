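#' Configuration for the synthetic longitudinal methylation cohort
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults emulate a longitudinal matched-pair blood-methylation study of
#' late-onset Alzheimer's disease: ~50 case/control pairs sampled at three
#' visits spanning 16 years before to 7 years after clinical onset, blood
#' drawn as a six-cell-type mixture dominated by granulocytes, and a set of
#' "clock" CpGs whose methylation tracks chronological age closely enough
#' that a linear clock built on them correlates with age at r of about 0.75.
#'
#' @param n_pairs number of matched case-control pairs.
#' @param visit_schedule planned sampling times in years relative to clinical
#'   onset (year 0); each visit is jittered by `U(-visit_jitter,
#'   visit_jitter)` and truncated to `[-16, 7]`.
#' @param visit_jitter half-width (years) of the uniform jitter on visits.
#' @param n_cpgs total number of CpG probes simulated.
#' @param n_stable_effect_cpgs CpGs carrying a constant case-control
#'   methylation offset of `effect_size_delta_beta` (random sign per CpG).
#' @param n_interaction_cpgs CpGs with a case-specific time slope
#'   (`interaction_slope` beta-units/year, random sign).
#' @param n_crossover_cpgs CpGs whose case-control difference flips sign
#'   between pre- and post-onset samples.
#' @param n_aging_cpgs CpGs drifting with chronological age in everyone
#'   (`aging_slope` beta-units/year, random sign).
#' @param n_clock_cpgs CpGs encoding chronological age linearly with slope
#'   `clock_slope`; the bundled toy clock is defined on these.
#' @param effect_size_delta_beta planted case-control difference on the beta
#'   (methylation fraction) scale, in (0, 1).
#' @param interaction_slope,aging_slope,clock_slope planted slopes in
#'   beta-units per year.
#' @param onset_age_range length-2 range (years) for uniform onset ages.
#' @param cell_mean_proportions named 6-vector of mean blood-cell
#'   proportions (must sum to 1): granulocytes, CD8+ T, CD4+ T, NK, B,
#'   monocytes.
#' @param cell_dirichlet_conc Dirichlet concentration governing per-sample
#'   variation of cell proportions around the mean.
#' @param noise_sd_logit SD of the per-entry Gaussian noise on the logit of
#'   beta.
#' @param subject_sd_logit SD of the per-subject-per-CpG random intercept
#'   (logit scale), inducing within-subject correlation across visits.
#' @param pair_sd_logit SD of the per-pair-per-CpG random intercept.
#' @param prop_male probability that a pair is male (controls are matched on
#'   sex).
#' @param apoe_case,apoe_control APOE e4 carrier probabilities.
#' @param smoking_rate probability of ever-smoker status.
#' @param missing_rate fraction of entries set to missing (NA).
#' @param n_pairs_no_post number of pairs whose post-onset visits are
#'   dropped (mirrors cases recruited without post-onset samples).
#' @param seed integer RNG seed; the generator is deterministic given the
#'   configuration.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_pairs = 50,
                          visit_schedule = c(-13, -6, 2),
                          visit_jitter = 2,
                          n_cpgs = 2000,
                          n_stable_effect_cpgs = 20,
                          n_interaction_cpgs = 10,
                          n_crossover_cpgs = 10,
                          n_aging_cpgs = 20,
                          n_clock_cpgs = 20,
                          effect_size_delta_beta = 0.05,
                          interaction_slope = 0.004,
                          aging_slope = 0.002,
                          clock_slope = 0.0019,
                          onset_age_range = c(67, 94),
                          cell_mean_proportions = c(granulocyte = 0.60,
                                                    cd8t = 0.08,
                                                    cd4t = 0.14,
                                                    nk = 0.06,
                                                    bcell = 0.04,
                                                    mono = 0.08),
                          cell_dirichlet_conc = 200,
                          noise_sd_logit = 0.25,
                          subject_sd_logit = 0.15,
                          pair_sd_logit = 0.07,
                          prop_male = 0.18,
                          apoe_case = 0.54,
                          apoe_control = 0.196,
                          smoking_rate = 0.30,
                          missing_rate = 0,
                          n_pairs_no_post = 0,
                          seed = 1L) {
  cfg <- list(n_pairs = n_pairs, visit_schedule = visit_schedule,
              visit_jitter = visit_jitter, n_cpgs = n_cpgs,
              n_stable_effect_cpgs = n_stable_effect_cpgs,
              n_interaction_cpgs = n_interaction_cpgs,
              n_crossover_cpgs = n_crossover_cpgs,
              n_aging_cpgs = n_aging_cpgs, n_clock_cpgs = n_clock_cpgs,
              effect_size_delta_beta = effect_size_delta_beta,
              interaction_slope = interaction_slope,
              aging_slope = aging_slope, clock_slope = clock_slope,
              onset_age_range = onset_age_range,
              cell_mean_proportions = cell_mean_proportions,
              cell_dirichlet_conc = cell_dirichlet_conc,
              noise_sd_logit = noise_sd_logit,
              subject_sd_logit = subject_sd_logit,
              pair_sd_logit = pair_sd_logit,
              prop_male = prop_male, apoe_case = apoe_case,
              apoe_control = apoe_control, smoking_rate = smoking_rate,
              missing_rate = missing_rate,
              n_pairs_no_post = n_pairs_no_post, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  counts <- c(cfg$n_pairs, cfg$n_cpgs, cfg$n_stable_effect_cpgs,
              cfg$n_interaction_cpgs, cfg$n_crossover_cpgs,
              cfg$n_aging_cpgs, cfg$n_clock_cpgs, cfg$n_pairs_no_post)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_mp("all counts in a cohort_config must be non-negative integers")
  }
  n_effect <- cfg$n_stable_effect_cpgs + cfg$n_interaction_cpgs +
    cfg$n_crossover_cpgs + cfg$n_aging_cpgs + cfg$n_clock_cpgs
  if (n_effect > cfg$n_cpgs) {
    stop_mp("effect CpG counts exceed n_cpgs")
  }
  if (abs(sum(cfg$cell_mean_proportions) - 1) > 1e-9) {
    stop_mp("cell_mean_proportions must sum to 1 (within 1e-9)")
  }
  if (length(cfg$cell_mean_proportions) < 2) {
    stop_mp("at least 2 cell types are required")
  }
  if (cfg$effect_size_delta_beta <= 0 || cfg$effect_size_delta_beta >= 1) {
    stop_mp("effect_size_delta_beta must lie in (0, 1)")
  }
  if (any(cfg$visit_schedule < -16) || any(cfg$visit_schedule > 7)) {
    stop_mp("visit_schedule times must lie within [-16, 7] years")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_mp("missing_rate must lie in [0, 1)")
  }
  if (cfg$n_pairs_no_post > cfg$n_pairs) {
    stop_mp("n_pairs_no_post cannot exceed n_pairs")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d matched pairs, %d CpGs, visits at (%s) +/- %g y jitter\n",
              x$n_pairs, x$n_cpgs,
              paste(x$visit_schedule, collapse = ", "), x$visit_jitter))
  cat(sprintf("  planted CpGs: %d stable (delta-beta %.3f), %d interaction, %d crossover, %d aging, %d clock\n",
              x$n_stable_effect_cpgs, x$effect_size_delta_beta,
              x$n_interaction_cpgs, x$n_crossover_cpgs,
              x$n_aging_cpgs, x$n_clock_cpgs))
  invisible(x)
}

cpg_ids <- function(n) sprintf("cg%08d", seq_len(n))

# Dirichlet draws via normalized gammas
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Generate a blood cell-type methylation reference panel
#'
#' Builds a synthetic CpG-by-cell-type matrix of mean methylation fractions
#' for reference-based deconvolution. A designated subset of discriminating
#' CpGs (roughly 20%, at least one per cell type) has a between-cell-type
#' beta spread of at least 0.3, guaranteeing an identifiable, full-rank
#' reference; the remaining rows vary only mildly across cell types.
#'
#' @param n_cpgs number of reference CpGs (must be >= `n_celltypes`).
#' @param n_celltypes number of cell types (>= 2). With 6 cell types the
#'   canonical blood panel names (granulocyte, cd8t, cd4t, nk, bcell, mono)
#'   are used.
#' @param seed integer RNG seed.
#'
#' @return A numeric matrix (CpG x cell type) in \[0, 1\] with a
#'   `discriminating` attribute listing the high-spread probe IDs.
#' @export
generate_reference_panel <- function(n_cpgs = 600, n_celltypes = 6,
                                     seed = 1L) {
  if (n_celltypes < 2) {
    stop_mp("invalid configuration: at least 2 cell types are required")
  }
  if (n_cpgs < n_celltypes) {
    stop_mp("n_cpgs must be at least n_celltypes")
  }
  set.seed(as.integer(seed))
  types <- if (n_celltypes == 6) {
    c("granulocyte", "cd8t", "cd4t", "nk", "bcell", "mono")
  } else {
    paste0("cell", seq_len(n_celltypes))
  }
  ids <- cpg_ids(n_cpgs)
  ref <- matrix(0, n_cpgs, n_celltypes, dimnames = list(ids, types))

  n_marker_per_type <- max(1L, floor(0.2 * n_cpgs / n_celltypes))
  n_marker <- n_marker_per_type * n_celltypes
  marker_rows <- seq_len(n_marker)
  marker_type <- rep(seq_len(n_celltypes), each = n_marker_per_type)
  for (i in seq_along(marker_rows)) {
    hi <- stats::runif(1, 0.80, 0.95)
    lo <- stats::runif(n_celltypes - 1, 0.05, 0.25)
    row <- rep(NA_real_, n_celltypes)
    row[marker_type[i]] <- hi
    row[-marker_type[i]] <- lo
    ref[marker_rows[i], ] <- row
  }
  if (n_marker < n_cpgs) {
    rest <- seq.int(n_marker + 1L, n_cpgs)
    mu <- stats::rbeta(length(rest), 1.2, 1.2)
    ref[rest, ] <- clip01(mu + stats::rnorm(length(rest) * n_celltypes,
                                            sd = 0.02))
  }
  attr(ref, "discriminating") <- ids[marker_rows]
  ref
}

# Deterministic per-config machinery shared by the longitudinal and external
# generators: CpG universe, per-cell-type baselines, effect classes and
# per-CpG planted signs/slopes. Regenerated from config$seed so both cohorts
# live on the same probe universe.
cohort_machinery <- function(config) {
  set.seed(derive_seed(config$seed, 0L))
  n <- config$n_cpgs
  ids <- cpg_ids(n)
  k <- length(config$cell_mean_proportions)
  types <- names(config$cell_mean_proportions)

  cls <- rep("null", n)
  idx <- 0L
  take <- function(m) {
    out <- if (m > 0) seq.int(idx + 1L, idx + m) else integer(0)
    idx <<- idx + m
    out
  }
  i_stable <- take(config$n_stable_effect_cpgs)
  i_inter <- take(config$n_interaction_cpgs)
  i_cross <- take(config$n_crossover_cpgs)
  i_aging <- take(config$n_aging_cpgs)
  i_clock <- take(config$n_clock_cpgs)
  cls[i_stable] <- "stable"; cls[i_inter] <- "interaction"
  cls[i_cross] <- "crossover"; cls[i_aging] <- "aging"
  cls[i_clock] <- "clock"

  # bimodal baseline typical of array methylation, mildly cell-type specific
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  mu <- numeric(n)
  mu[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 8)
  mu[comp == 2] <- stats::rbeta(sum(comp == 2), 8, 2)
  mu[comp == 3] <- stats::rbeta(sum(comp == 3), 5, 5)
  reference <- clip01(mu + matrix(stats::rnorm(n * k, sd = 0.02), n, k),
                      eps = 0.01)
  dimnames(reference) <- list(ids, types)
  # effect-bearing CpGs start mid-range so planted shifts survive clipping;
  # clock CpGs are pinned to 0.5 across cell types so the toy clock is exact
  mid <- c(i_stable, i_inter, i_cross, i_aging)
  if (length(mid)) {
    reference[mid, ] <- clip01(stats::runif(length(mid), 0.35, 0.65) +
                                 matrix(stats::rnorm(length(mid) * k,
                                                     sd = 0.02),
                                        length(mid), k), eps = 0.01)
  }
  if (length(i_clock)) reference[i_clock, ] <- 0.5

  sign_vec <- numeric(n)
  sign_vec[c(i_stable, i_cross)] <- sample(c(-1, 1),
                                           length(c(i_stable, i_cross)),
                                           replace = TRUE)
  slope_vec <- numeric(n)
  slope_vec[i_inter] <- sample(c(-1, 1), length(i_inter), replace = TRUE) *
    config$interaction_slope
  slope_vec[i_aging] <- sample(c(-1, 1), length(i_aging), replace = TRUE) *
    config$aging_slope
  slope_vec[i_clock] <- config$clock_slope

  design <- sample(c("I", "II"), n, replace = TRUE, prob = c(0.4, 0.6))

  list(ids = ids, class = cls, reference = reference, sign = sign_vec,
       slope = slope_vec, design = design, types = types,
       clock_idx = i_clock)
}

# toy linear age clock defined on the planted clock CpGs: with per-CpG slope
# c and baseline 0.5 anchored at age 60, the equal-weight inversion
# intercept + sum(w * beta) recovers age exactly in expectation
toy_clock_from_machinery <- function(mach, clock_slope) {
  ids <- mach$ids[mach$clock_idx]
  if (!length(ids)) return(NULL)
  w <- rep(1 / (length(ids) * clock_slope), length(ids))
  names(w) <- ids
  clock_definition(name = "toy_age_clock",
                   intercept = 60 - 0.5 / clock_slope,
                   weights = w, calibration = "identity",
                   is_age_estimator = TRUE)
}

# planted mean shift for one sample at every CpG (vector over CpGs)
planted_shift <- function(mach, delta, ad, time, age, attenuation = 1) {
  shift <- numeric(length(mach$ids))
  cls <- mach$class
  if (ad == 1) {
    st <- cls == "stable"
    shift[st] <- shift[st] + mach$sign[st] * delta * attenuation
    cr <- cls == "crossover"
    pre_sign <- if (time < 0) 1 else -1
    shift[cr] <- shift[cr] + mach$sign[cr] * pre_sign * delta * attenuation
    it <- cls == "interaction"
    shift[it] <- shift[it] + mach$slope[it] * time * attenuation
  }
  ag <- cls == "aging"
  shift[ag] <- shift[ag] + mach$slope[ag] * (age - 75)
  ck <- cls == "clock"
  shift[ck] <- shift[ck] + mach$slope[ck] * (age - 60)
  shift
}

#' Generate a synthetic longitudinal matched-pair methylation cohort
#'
#' Simulates an EPIC-style beta-value matrix, a sample sheet and a ground
#' truth record for a matched case-control cohort sampled longitudinally
#' around clinical Alzheimer's disease onset. Each sample's baseline
#' methylation is a convex mixture of six cell-type reference profiles
#' (per-sample Dirichlet cell proportions); Gaussian noise and subject/pair
#' random intercepts are added on the logit scale; planted effects (stable
#' case-control offsets, case-specific slopes, crossover reversals, aging
#' drift, age-encoding clock CpGs) are applied as shifts on the beta scale,
#' and everything is clipped to \[0, 1\]. Matched controls inherit the
#' case's onset age, so time-to-onset is defined for both pair members, and
#' are matched on sex and baseline age within one year.
#'
#' @param config a [cohort_config()].
#'
#' @return A list with elements
#'   \describe{
#'     \item{beta}{CpG x sample matrix of methylation fractions (NA where
#'       masked by `missing_rate`).}
#'     \item{samples}{sample sheet data.frame: `sample_id`, `subject_id`,
#'       `pair_id`, `ad` (0/1), `sex`, `age`, `onset_age`, `time_to_onset`,
#'       `apoe_e4`, `smoker`, `rtl`, `visit`.}
#'     \item{truth}{ground truth: per-CpG `class`
#'       (null/stable/interaction/crossover/aging/clock), signed
#'       `true_delta_beta` and `true_slope`, per-sample true
#'       `cell_proportions`, per-subject `onset_age`, the generating
#'       machinery (`reference`, `design`) and the bundled `toy_clock`
#'       (a [clock_definition()]).}
#'   }
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  mach <- cohort_machinery(config)
  set.seed(derive_seed(config$seed, 1L))

  np <- config$n_pairs
  onset <- stats::runif(np, config$onset_age_range[1],
                        config$onset_age_range[2])
  sex <- ifelse(stats::runif(np) < config$prop_male, "M", "F")
  ctrl_offset <- stats::runif(np, -1, 1)
  no_post <- seq_len(config$n_pairs_no_post)

  rows <- list()
  for (p in seq_len(np)) {
    times <- config$visit_schedule +
      stats::runif(length(config$visit_schedule),
                   -config$visit_jitter, config$visit_jitter)
    times <- sort(pmin(pmax(times, -16), 7))
    if (p %in% no_post) {
      keep <- times < 0
      if (!any(keep)) keep[1] <- TRUE
      times <- times[keep]
    }
    for (ad in c(1L, 0L)) {
      subj <- sprintf("s%03d_%s", p, if (ad == 1) "case" else "ctrl")
      age0 <- onset[p] + if (ad == 1) 0 else ctrl_offset[p]
      for (v in seq_along(times)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_v%d", subj, v),
          subject_id = subj,
          pair_id = sprintf("p%03d", p),
          ad = ad, sex = sex[p],
          age = age0 + times[v],
          onset_age = onset[p],
          time_to_onset = times[v],
          visit = v,
          stringsAsFactors = FALSE)
      }
    }
  }
  sheet <- do.call(rbind, rows)

  subj_tab <- unique(sheet[, c("subject_id", "ad")])
  subj_tab$apoe_e4 <- stats::rbinom(nrow(subj_tab), 1,
                                    ifelse(subj_tab$ad == 1,
                                           config$apoe_case,
                                           config$apoe_control))
  subj_tab$smoker <- stats::rbinom(nrow(subj_tab), 1, config$smoking_rate)
  # per-subject telomere baseline and attrition; cases attrite slightly faster
  subj_tab$rtl0 <- stats::rnorm(nrow(subj_tab), 1.6, 0.15)
  subj_tab$rtl_slope <- stats::rnorm(nrow(subj_tab),
                                     ifelse(subj_tab$ad == 1, -0.007, -0.005),
                                     0.002)
  sheet <- merge(sheet, subj_tab, by = c("subject_id", "ad"), sort = FALSE)
  sheet <- sheet[order(sheet$pair_id, -sheet$ad, sheet$visit), ]
  rownames(sheet) <- NULL
  sheet$rtl <- sheet$rtl0 + sheet$rtl_slope * (sheet$age - 50) +
    stats::rnorm(nrow(sheet), 0, 0.02)
  sheet$rtl0 <- sheet$rtl_slope <- NULL

  ns <- nrow(sheet)
  n <- config$n_cpgs
  k <- length(config$cell_mean_proportions)

  props <- rdirichlet(ns, config$cell_mean_proportions *
                        config$cell_dirichlet_conc)
  dimnames(props) <- list(sheet$sample_id, mach$types)

  base <- mach$reference %*% t(props)                     # n x ns
  subj_ids <- unique(sheet$subject_id)
  pair_ids <- unique(sheet$pair_id)
  subj_int <- matrix(stats::rnorm(n * length(subj_ids),
                                  sd = config$subject_sd_logit),
                     n, length(subj_ids), dimnames = list(NULL, subj_ids))
  pair_int <- matrix(stats::rnorm(n * length(pair_ids),
                                  sd = config$pair_sd_logit),
                     n, length(pair_ids), dimnames = list(NULL, pair_ids))
  eta <- logit(clip01(base, eps = 1e-4)) +
    subj_int[, sheet$subject_id] + pair_int[, sheet$pair_id] +
    matrix(stats::rnorm(n * ns, sd = config$noise_sd_logit), n, ns)
  beta <- expit(eta)

  shift <- vapply(seq_len(ns), function(i) {
    planted_shift(mach, config$effect_size_delta_beta, sheet$ad[i],
                  sheet$time_to_onset[i], sheet$age[i])
  }, numeric(n))
  beta <- clip01(beta + shift)
  dimnames(beta) <- list(mach$ids, sheet$sample_id)

  if (config$missing_rate > 0) {
    beta[stats::runif(length(beta)) < config$missing_rate] <- NA_real_
  }

  true_delta <- ifelse(mach$class %in% c("stable", "crossover"),
                       mach$sign * config$effect_size_delta_beta, 0)
  truth <- list(
    cpg_id = mach$ids,
    class = mach$class,
    true_delta_beta = true_delta,
    true_slope = mach$slope,
    cell_proportions = props,
    onset_age = stats::setNames(
      onset[as.integer(sub("^s(\\d+)_.*$", "\\1", subj_tab$subject_id))],
      subj_tab$subject_id),
    reference = mach$reference,
    design = stats::setNames(mach$design, mach$ids),
    toy_clock = toy_clock_from_machinery(mach, config$clock_slope),
    config = config)

  list(beta = beta, samples = sheet, truth = truth)
}

#' Generate a cross-sectional external validation cohort
#'
#' Produces a one-sample-per-subject cohort on the same CpG universe as a
#' cohort generated from the same configuration, with a shifted demographic
#' composition (sex ratio and APOE e4 enrichment emulating an external
#' clinical sample) and planted case-control effects attenuated by a
#' configurable factor to emulate partial replication.
#'
#' @param config the [cohort_config()] that generated the discovery cohort.
#' @param truth the `truth` element returned by [generate_cohort()]; its CpG
#'   universe must match `config` (checked).
#' @param n_controls,n_cases cross-sectional group sizes.
#' @param shift list of demographic overrides: `prop_male`, `apoe_case`,
#'   `apoe_control`.
#' @param attenuation multiplier in \[0, 1\] on the planted case-control
#'   effects (0 = no signal, 1 = full replication).
#' @param seed integer RNG seed for this cohort (independent of the
#'   discovery cohort's stream).
#'
#' @return A list with `beta` (CpG x sample) and `samples` (sample sheet
#'   with `sample_id`, `subject_id`, `ad`, `sex`, `age`, `apoe_e4`,
#'   `smoker`).
#' @export
generate_external_cohort <- function(config, truth,
                                     n_controls = 324, n_cases = 146,
                                     shift = list(prop_male = 0.43,
                                                  apoe_case = 0.77,
                                                  apoe_control = 0.23),
                                     attenuation = 0.5,
                                     seed = derive_seed(config$seed, 7919L)) {
  validate_cohort_config(config)
  mach <- cohort_machinery(config)
  if (!identical(mach$ids, truth$cpg_id)) {
    stop_mp("alignment error: truth CpG universe does not match config")
  }
  set.seed(as.integer(seed))

  ns <- n_controls + n_cases
  ad <- c(rep(0L, n_controls), rep(1L, n_cases))
  sex <- ifelse(stats::runif(ns) < shift$prop_male, "M", "F")
  age <- ifelse(ad == 1, stats::runif(ns, 67, 93), stats::runif(ns, 65, 81))
  apoe <- stats::rbinom(ns, 1, ifelse(ad == 1, shift$apoe_case,
                                      shift$apoe_control))
  smoker <- stats::rbinom(ns, 1, config$smoking_rate)
  ids <- sprintf("ext%04d", seq_len(ns))
  sheet <- data.frame(sample_id = ids, subject_id = ids, ad = ad, sex = sex,
                      age = age, apoe_e4 = apoe, smoker = smoker,
                      stringsAsFactors = FALSE)

  n <- config$n_cpgs
  props <- rdirichlet(ns, config$cell_mean_proportions *
                        config$cell_dirichlet_conc)
  base <- mach$reference %*% t(props)
  eta <- logit(clip01(base, eps = 1e-4)) +
    matrix(stats::rnorm(n * ns,
                        sd = sqrt(config$noise_sd_logit^2 +
                                    config$subject_sd_logit^2)), n, ns)
  beta <- expit(eta)
  # cases are sampled cross-sectionally ~1 year after onset
  shift_mat <- vapply(seq_len(ns), function(i) {
    planted_shift(mach, config$effect_size_delta_beta, sheet$ad[i],
                  time = 1, age = sheet$age[i], attenuation = attenuation)
  }, numeric(n))
  beta <- clip01(beta + shift_mat)
  dimnames(beta) <- list(mach$ids, ids)

  list(beta = beta, samples = sheet)
}
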