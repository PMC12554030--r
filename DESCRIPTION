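Package: memoscore
Title: Multiomics Risk Scores for Prediction of Episodic Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Construction and evaluation of epidemiological (CAIDE),
    metabolomic (MRS) and polygenic (LASSO-based and continuous-shrinkage
    Bayesian) risk scores for episodic memory, with a synthetic cohort
    generator emulating the statistical structure of a late-adulthood
    birth-cohort study. Provides genome-wide L1-penalized
    regression with unpenalized covariates, per-variant association
    scans, inverse-variance fixed-effect meta-analysis, a gamma-gamma
    global-local shrinkage Gibbs sampler over linkage-disequilibrium
    blocks, allele harmonization and scoring, and a nested linear-model
    evaluation grid with incremental R-squared and layered
    Benjamini-Hochberg false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
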