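Package: methylpanel
Title: Longitudinal Blood DNA-Methylation Biomarker Panels for Dementia
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving and evaluating blood DNA-methylation (DNAm)
    biomarkers of late-onset Alzheimer's disease from longitudinal matched
    case-control cohorts. Implements probe-level quality masking, blacklist
    filtering, beta-mixture quantile (BMIQ-style) normalization and K-nearest
    neighbour imputation for EPIC-style beta-value matrices; reference-based
    blood-cell deconvolution by sum-to-one-constrained non-negative least
    squares; a coefficient-table-driven linear epigenetic-clock engine with
    delta-age computation and a low-outlier replacement rule; a CpG-wise
    longitudinal mixed-model scan with nested random intercepts, genomic
    inflation, Benjamini-Hochberg adjustment and a composite selection rule
    producing a signed-sum methylation panel score; from-scratch sparse
    partial least squares discriminant analysis with balanced-error-rate
    cross-validation tuning; and logistic, Cox and C-statistic evaluation of
    candidate biomarkers, including external-cohort validation. A synthetic
    longitudinal cohort generator with known ground truth makes the whole
    pipeline testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    survival,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    MASS
Config/testthat/edition: 3
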