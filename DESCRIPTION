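Package: urinmr
Title: Urine 1H-NMR Metabolomics Screening with OPLS-DA Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for urine 1H-NMR metabolomics class
    discrimination: seeded simulation of urine proton NMR cohorts from a
    built-in metabolite signature library, TSP reference normalization,
    fixed-width spectral binning with water-region exclusion, Pareto scaling,
    OPLS-DA (NIPALS with orthogonal signal deflation) with cross-validated Q2
    and stratified holdout validation, statistical total correlation
    spectroscopy (STOCSY) marker identification, per-metabolite ROC/AUC
    ranking, and the full diagnostic-accuracy panel (sensitivity, specificity,
    predictive values, likelihood ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, jsonlite, yaml, pROC, pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
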