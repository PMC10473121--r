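# methylpanel

Tools for deriving and evaluating blood DNA-methylation (DNAm) biomarkers
of late-onset Alzheimer's disease (AD) from longitudinal matched
case-control cohorts — the setting where each AD case is paired with a
sex- and age-matched control and both are sampled repeatedly from up to
sixteen years before to several years after the case's clinical onset.

The package is aimed at epigenetic epidemiologists who want a tested,
reusable implementation of this analysis style without access to
restricted cohort data: every stage runs end-to-end on a bundled synthetic
cohort generator with known ground truth.

## What it computes

**The longitudinal panel.** Each CpG's beta value (methylation fraction,
β ∈ [0, 1]) is modelled with a nested random-intercept linear mixed model

    β ~ AD + t + AD·t + APOEε4 + smoking + granulocyte
        + (1 | pair) + (1 | subject)

where *t* is years to/after onset. A CpG enters the panel when the AD
term has p < 0.001 **and** |β̂_AD| ≥ 0.05 **and** the fitted case-control
difference β̂_AD + β̂_AD·t · t keeps its sign from the earliest to the
latest observed time (no crossover). The panel score per sample is the
signed sum Σᵢ sᵢ βᵢ with sᵢ = ±1 by direction of association (an
effect-size-weighted variant is available). Scan-level diagnostics include
the genomic inflation factor λ and Benjamini–Hochberg q-values.

**Around it**, the package provides detection-p masking, blacklist
filtering, complete-case selection, BMIQ-style beta-mixture quantile
normalization and KNN imputation; blood cell deconvolution by sum-to-one
constrained non-negative least squares; a coefficient-table-driven linear
epigenetic-clock engine with delta ages (Δ = clock − chronological age)
and a low-outlier replacement rule; from-scratch sparse PLS-DA with
balanced-error-rate cross-validation tuning; and logistic / Cox /
C-statistic evaluation with external-cohort validation. See the methods
vignette (`vignettes/methylpanel-methods.Rmd`) for the models and the
numerical choices.

## Worked example

Simulate a 40-pair cohort (2,000 CpGs, 15 with a planted stable
case-control difference of 0.08), scan it, select the panel, and validate
on a shifted external cohort where the planted effects are attenuated by
half:

```r
library(methylpanel)

cfg <- cohort_config(n_cpgs = 2000, n_pairs = 40,
                     n_stable_effect_cpgs = 15, n_interaction_cpgs = 5,
                     n_crossover_cpgs = 10, n_aging_cpgs = 10,
                     n_clock_cpgs = 20, effect_size_delta_beta = 0.08,
                     seed = 7)
coh <- generate_cohort(cfg)
sheet <- coh$samples
sheet$granulocyte <- estimate_proportions(coh$beta,
                                          coh$truth$reference)$granulocyte

res <- ewas_scan(coh$beta, sheet, lmm_spec())
genomic_lambda(na.omit(res$p))
#> [1] 1.08
panel <- select_panel(res)
panel
#> Methylation panel: 14 CpGs (6 hyper-, 8 hypomethylated in cases);
#> p < 0.001, |effect| >= 0.05

ext <- generate_external_cohort(cfg, coh$truth, n_controls = 324,
                                n_cases = 146, attenuation = 0.5, seed = 8)
ext$samples$granulocyte <- estimate_proportions(ext$beta,
                                                coh$truth$reference)$granulocyte
val <- validate_external(panel, ext$beta, ext$samples)
round(c(covariates_only = val$auc_covariates_only,
        with_panel = val$auc_with_score), 3)
#> covariates_only      with_panel
#>           0.888           0.959
val$n_concordant
#> [1] 14
```

Reading the output: λ = 1.08 says the scan's test statistics are close to
their null calibration (1.0 = no inflation). The panel recovered 14 of
the 15 planted stable CpGs and none of the crossover or null CpGs. On the
external cohort the panel score raises the covariate-adjusted AUC from
0.888 to 0.959, its per-SD odds ratio is ≈ 9.5, and all 14 CpGs keep
their direction of association — the attenuated-replication behaviour the
generator plants. (In-sample evaluation of the discovery cohort itself
separates cases perfectly; such AUCs are circular and are labelled
in-sample throughout.)

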