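---
title: "Deriving longitudinal blood-methylation biomarker panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving longitudinal blood-methylation biomarker panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylpanel)
```

## Scope and scientific setting

`methylpanel` implements an analysis pipeline for deriving blood
DNA-methylation (DNAm) biomarkers of late-onset Alzheimer's disease (AD)
from a longitudinal matched case-control design: case/control pairs matched
on sex and baseline age, each sampled one to three times in a window from
roughly sixteen years before to seven years after the case's clinical
onset. The pipeline covers

1. probe-level preprocessing of EPIC-style beta-value matrices,
2. reference-based blood cell deconvolution,
3. a linear epigenetic-clock engine with delta-age computation,
4. a CpG-wise longitudinal mixed-model scan and a composite selection rule
   producing a signed-sum methylation panel,
5. from-scratch sparse partial least squares discriminant analysis
   (sPLS-DA) for cross-sectional multivariate selection, and
6. logistic / Cox / C-statistic evaluation, including external-cohort
   validation.

Because real cohorts of this kind are access-restricted, the package ships
a synthetic cohort generator with a known ground truth; every downstream
stage is exercised and tested against it. This vignette documents the
models, the defaults and why they were chosen, the numerical decisions,
and what the synthetic experiments do and do not demonstrate about real
data.

## The synthetic cohort generator

The generator is first-class, tested code: its defaults *are* the study
conditions the rest of the package is validated under.

**Design.** `cohort_config()` defaults to 50 case-control pairs with three
planned visits at (−13, −6, +2) years relative to onset, each jittered by
U(−2, 2) years and truncated to [−16, 7], approximating three sampling
windows (long before, before, and after onset). Onset ages are uniform on
[67, 94] (late-onset disease); 18% of pairs are male; APOE ε4 carriage is
54% in cases and 19.6% in controls. Controls inherit their matched case's
onset age so that "time to onset" is defined for both members of a pair;
the matched control's age differs from the case's by at most one year. A
config flag (`n_pairs_no_post`) reproduces pairs recruited without
post-onset samples.

**Methylation model.** Each sample's baseline methylation is a convex
mixture of six cell-type reference profiles (granulocytes 60%, CD8+ T 8%,
CD4+ T 14%, NK 6%, B 4%, monocytes 8% on average, per-sample Dirichlet
variation with concentration 200). Noise is additive Gaussian on the logit
of beta — a per-entry term (SD 0.25), a per-subject-per-CpG random
intercept (SD 0.15) inducing within-subject correlation, and a
per-pair-per-CpG intercept (SD 0.07) — followed by the inverse logit.
Planted effects are then applied as shifts on the beta scale and the
result clipped to [0, 1]: effect sizes are therefore specified in the
units practitioners report (methylation-fraction differences), while the
noise respects the bounded support.

The noise SDs were calibrated once, jointly, against two study-level
anchors: (i) a linear clock built on the planted clock CpGs should
correlate with chronological age at r ≈ 0.70–0.80, the range blood clocks
achieve in cohorts of this age span; and (ii) CpGs carrying a stable
case-control difference of ≥ 0.05 should be detectable at p < 0.001 with
about 40–50 pairs, which is the detectability the original study design
exhibited. The implied per-CpG standard error of the AD term is ≈ 0.014
beta units. Noisier settings would contradict anchor (ii); quieter ones
would push the clock correlation above anchor (i) unless the clock slope
were retuned, which is why the two are calibrated together (clock CpGs use
a slope of 0.0019 beta units/year around a baseline of 0.5 anchored at age
60; the bundled toy clock is the exact linear inversion of that encoding).

**Planted effect classes.** Each CpG belongs to exactly one class:
`null`, `stable` (constant case-control offset ±Δβ, default 0.05),
`interaction` (case-specific slope, 0.004/yr), `crossover` (offset +Δβ
before onset, −Δβ after — generated explicitly so the selection rule's
exclusion branch is testable), `aging` (drift with chronological age in
everyone, 0.002/yr), and `clock`. The ground-truth object records classes,
signed effects, true cell proportions and onset ages.

**External cohort.** `generate_external_cohort()` reuses the same CpG
universe and effect assignment but draws a cross-sectional sample (one
visit per subject, cases ~1 year post-onset) with a shifted demography
(43% male; ε4 77% in cases / 23% in controls) and attenuates the planted
case-control effects by a configurable factor (default 0.5) to emulate
partial replication across cohorts.

**What the generator does not emulate:** probe-type chemistry beyond a
design-class label, raw array intensities and detection chemistry, genetic
structure beyond a binary ε4 indicator, batch effects, spatially
correlated (region-level) methylation, and cell-type-specific disease
effects. Passing tests therefore demonstrate the *statistical machinery* —
calibration, recovery, selection behaviour — under a faithful noise and
design model; they cannot certify biological replication in real cohorts.

## Preprocessing

Detection-p masking uses a strict inequality (entries with p > 0.05 become
missing); masking precedes normalization, and the order is an explicit
argument of the pipeline rather than a hidden convention. Blacklist
filtering removes the union of user-supplied probe sets (multimapping,
SNP-proximal, meQTL, sex chromosomes) and reports per-set counts; the
complete-case rule then removes every probe with any missing value,
reporting in/removed/out counts that must reconcile exactly. Batch
correction is deliberately absent.

The BMIQ-style step is a simplified re-implementation of beta-mixture
quantile normalization: per sample, a three-state (unmethylated /
hemi-methylated / methylated) beta mixture is fitted by EM to each probe
design class, and design-II values are quantile-mapped state-by-state onto
the design-I mixture. EM updates use responsibility-weighted
method-of-moments for the beta shapes (fast and numerically stable on
[0, 1] data); initialization is a 1-d k-means at centres (0.15, 0.5,
0.85); convergence is declared at a log-likelihood change < 1e-4 within
100 iterations, and a non-converged sample is returned unchanged with a
warning. Full fidelity to the original method's state-assignment edge
cases is not claimed, and the pipeline can skip normalization entirely.

KNN imputation (k = 10 by default — the method's customary default, since
the upstream description names KNN but not k) replaces each missing entry
by the inverse-distance-weighted mean of the k nearest samples observed at
that probe, with distances computed as mean squared differences over
mutually observed probes. Observed entries are never altered.

## Cell deconvolution

Proportions are estimated per sample by least squares on the reference
profiles under non-negativity and sum-to-one constraints. The equality
constraint is imposed by augmenting the system with a heavily weighted
(λ = 1000) row of ones inside a Lawson–Hanson non-negative least-squares
solve, followed by exact renormalization; on noise-free convex mixtures
this recovers the composition to machine precision, and the constraint
set (equality, not "≤ 1") reflects the compositional nature of blood cell
fractions. A rank check rejects degenerate references. The granulocyte
fraction — the dominant cell type — is the covariate carried into all
downstream models.

## Epigenetic clocks

The clock engine is coefficient-table-driven:
`value = calibration(intercept + Σ wᵢ βᵢ)`. Published coefficient sets are
not bundled (size and licensing); the CSV + JSON schema accepts them
verbatim. Two calibrations are provided: identity, and the standard
adult-age-anchored piecewise-log form (anchor default 20), whose two
branches agree at the anchor — the continuity is asserted in tests.
Delta age is clock minus chronological age (positive = accelerated
epigenetic aging); pace-style scores set `is_age_estimator = FALSE` and
pass through raw. The low-outlier rule replaces values strictly below
mean − 3 SD by the second-lowest *distinct* original value (the tie rule:
tied minima are all replaced by that same value); it is applied per clock
and is idempotent on the data patterns it is meant for.

## The longitudinal mixed-model scan and panel

The model per response (clock delta, cell proportion, or single-CpG beta)
is a Gaussian linear mixed model with nested random intercepts:

    y ~ AD + time + AD:time + APOE ε4 + smoking + granulocyte
        + (1 | pair) + (1 | subject)

with time in years to/after onset (chronological age available as an
alternative scale). Estimation is REML via `lme4`; the CpG-wise scan fits
one template model and reuses it with `lme4::refit` per probe, which makes
a 5,000-probe scan a matter of a minute or two on one core. Fixed-effect
p-values use the Wald normal reference by default — with ~230–240
observations and ~78 residual degrees of freedom the normal and t
references differ negligibly, and a t-with-residual-df option is exposed.
Singular fits (a variance component pinned at zero) and non-convergence
are flagged per probe, zero-variance probes are skipped with a note, and
the scan always continues.

The composite panel rule selects probes with (i) AD-term p < 0.001,
(ii) |AD estimate| ≥ 0.05 beta units, and (iii) no crossover: the fitted
case-control difference `β_AD + β_AD:time · t`, evaluated at the earliest
and latest observed times, must have the same sign. Operationalizing
"direction unchanged before and after onset" through the *fitted*
difference at the observed time extremes keeps the rule defined for
subjects without post-onset samples. These are exploratory thresholds —
Benjamini–Hochberg q-values are always computed and reported alongside,
and the genomic inflation factor λ (median observed χ²₁ over its null
median) is the scan-level calibration diagnostic. The panel score is the
signed sum Σ sᵢβᵢ with sᵢ = ±1 by direction of association; a weighted
variant uses the LMM effect sizes as weights.

## Sparse PLS-DA

The sPLS-DA is written from scratch in the NIPALS style: classes are
one-hot coded, both blocks centred and scaled, and per component the
X-loading is the soft-thresholded cross-covariance direction — the
threshold set so that exactly `keepX` entries remain nonzero, then
renormalized to unit length — alternated with the Y-loading update until
convergence (tol 1e-6, max 500 iterations), followed by regression-mode
deflation of both blocks. In the dense limit (keepX = p) the first
loading equals the leading singular direction of X'Y, which is the
oracle the tests check against. Two numerical conventions make fits
reproducible: the largest-magnitude entry of each loading is made
positive, and prediction ties break to the first class in sorted label
order. Prediction projects new samples through the rotation
W(PᵀW)⁻¹ and assigns the class with the largest predicted indicator value
(maximum-distance rule; a nearest-centroid rule is available — the
prediction rule is a genuinely open choice and both conventions are
exposed).

Tuning minimizes the balanced error rate (mean per-class misclassification
fraction) under stratified 3-fold cross-validation repeated 50 times with
seeded reshuffles, choosing `keepX` per component sequentially (ties to
the sparser model). Subject-level scores are formed from *raw* beta values
weighted by the loadings — matching the biomarker construction convention
— with centred scoring available behind a flag. In-sample evaluation of
such scores is partially circular; every report in this package labels
in-sample AUCs as in-sample.

## Risk evaluation

Continuous predictors are z-scored (sample SD, computed within the cohort
being analysed) so that odds and hazard ratios read per one SD increase;
binary indicators stay on their natural scale. Logistic models are fitted
by `glm` with Wald CIs and a perfect-separation flag; Cox models by
`survival::coxph` with Efron tie handling (ties are plausible at annual
onset resolution), time measured from the baseline sample to onset for
cases and to last follow-up (censored) for controls — the censoring
convention is an assumption, stated here, since matched designs leave it
open. The C-statistic is computed from midranks (equal to exhaustive
case-control pair counting, ties credited one half). Telomere-length
slopes are per-subject OLS of RTL on age at sampling and serve as a
comparison biomarker. External validation scores the panel on the
external cohort, fits covariate-adjusted logistic models with and without
the score, and reports per-SD ORs, both AUCs, and per-CpG univariate
replication with direction-concordance counts. Collinearity among
biomarkers is the reason joint models are fitted per biomarker;
a joint Cox fit of panel + scores + RTL slope + covariates is supported
and per-term significance reported.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run, by design, at desk
scale: a 600-CpG reference with 50 noise-free mixtures for the
deconvolution recovery; 1,000 null CpGs at 40 pairs for type-I-error
calibration of the scan; 5,000 CpGs (20 stable, 20 crossover, Δβ = 0.08)
at 40 pairs for the panel operating characteristics; 60 × 100 null
matrices under 3-fold × 50-repeat cross-validation for the sPLS-DA
honesty check; and exhaustive small-n oracles for Cox, the C-statistic
and Benjamini–Hochberg. These sizes were chosen as the smallest at which
the Monte-Carlo bands quoted in the tests are meaningful.

## Known limitations

* The BMIQ-style normalization is a simplified re-implementation; its
  state assignment can differ from the original on boundary probes.
* Wald (normal) p-values are mildly anticonservative in very small
  designs; use the t option below ~30 subjects.
* The generator's logit-Gaussian noise has no heavy tails and no
  probe-specific variance structure; real arrays show both.
* The sPLS-DA implements the single-block, classification-mode variant
  only.
* Reference-free deconvolution, region-level (DMR) calling, and GAMM
  smoothing are out of scope; plots of trajectories should use a simple
  loess for display.
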