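Package: radstack
Title: Tumoral and Peritumoral CT Radiomics with Stacked Response Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for predicting immunotherapy response in
    non-small cell lung cancer from CT radiomics and clinical covariates.
    Generates synthetic cohorts with planted, recoverable signal; computes
    per-voxel 3D gray-level co-occurrence Haralick texture maps plus a
    gradient map and summarises them over tumoral and peritumoral regions
    into 63 named features per region; performs two-stage random-forest
    feature selection; trains the matrix of region, clinical, stacked and
    direct classifiers with patient-level stratified folds and strictly
    out-of-fold probability features; learns Bayesian network structure over
    discretized clinical variables by BDeu-scored hill climbing and fits an
    exact discrete classifier on the result; contrasts predicted groups by
    Kaplan-Meier curves, log-rank tests and restricted mean survival time;
    and renders hypothesis-grounded natural-language reports ranked by an
    answer relevancy metric with a deterministic offline embedder.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    ranger,
    pROC,
    survival,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
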