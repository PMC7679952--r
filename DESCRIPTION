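Package: ctcnet
Title: Cerebello-Thalamo-Cortical Network Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for graph-theoretic and model-based
    analysis of cerebello-thalamo-cortical brain networks in pediatric
    cancer-survivor cohorts. Builds Fisher-z functional connectivity
    matrices from regional fMRI time courses, thresholds them at
    proportional densities with a minimum-density search and fragmentation
    diagnostics, computes global efficiency and within-module degree
    z-scores, tests group differences with subject-label permutation nulls,
    learns directed effective-connectivity structure by Gaussian-BIC
    hill-climbing Bayesian network search with stratified comparison and a
    sex-by-impairment interaction ANOVA on edge weights, and provides
    cohort statistics (impairment classification, Wald proportion
    intervals, sex-stratified morphometry-exposure models, Pearson
    correlations, Benjamini-Yekutieli FDR control). Includes a synthetic
    cohort generator emulating the statistical structure of the study
    inputs so the full pipeline runs without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    car,
    stats,
    utils,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
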