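Package: eegtda
Title: Topological Data Analysis of Oddball EEG for Cognitive Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end pipeline for studying mild cognitive impairment with
    multichannel EEG and topological data analysis. Simulates oddball-paradigm
    EEG studies (two cohorts, event markers, eye-blink artifacts, MoCA
    scores), preprocesses recordings (zero-phase band-pass filtering,
    stimulus-locked epoching, empirical-mode-decomposition artifact rejection
    at an amplitude threshold), extracts persistent-homology features from
    embedded point clouds (Vietoris-Rips filtration, Betti-1 curves,
    normalized persistence entropy, persistence ratios), compares cohorts with
    rank-based statistics and effect sizes, projects feature tables to two
    dimensions with UMAP or t-SNE, and evaluates leave-one-subject-out
    random-forest classification and cognitive-score regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    randomForest,
    pROC,
    jsonlite,
    uwot,
    Rtsne,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
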