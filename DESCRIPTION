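Package: metaboCP
Title: Conformal Phenotype Prediction for Two-Cohort LC-MS Metabolomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for cerebrospinal-fluid metabolomics
    phenotype classification across two LC-MS cohorts: post-quantification
    feature filtering (blank-based contaminant removal, dilution-series
    correlation, QC coefficient-of-variation), QC-anchored LOESS run-order
    drift correction, cross-cohort feature matching within ppm/retention-time
    windows, age-association and presence filtering, elastic-net signature
    selection with a balanced-fold one-standard-error rule, transductive
    Mondrian (class-conditional) conformal prediction yielding per-patient
    phenotype p-values with efficiency and calibration curves, and
    longitudinal disease-monitoring statistics (PCA projection, ANOSIM,
    paired Wilcoxon, sex-adjusted fold changes, multilevel clinical
    associations). Includes a synthetic-data generator that emulates the
    two-cohort study design with planted discriminatory features, age
    confounders, batch shifts, run-order drift and treated patients whose
    signatures drift between phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    e1071,
    vegan,
    nlme
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    emmeans,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
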