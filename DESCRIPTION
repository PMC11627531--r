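Package: gazeperm
Title: Cluster-Based Permutation Analysis for Multi-Method Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing visual-world eye-tracking time courses
    recorded with heterogeneous methods (infrared trackers, frame-by-frame
    manual annotation of webcam video, and appearance-based gaze estimators
    such as WebGazer). Provides region-of-interest binning and binarization
    of gaze streams, per-time-bin binomial-logit mixed models with
    carry-forward fallback rules, cluster-mass permutation inference under
    within-subject and between-subject shuffling schemes, analysis-, cluster-
    and peak-window effect sizes, smooth-pursuit spatial-offset analysis,
    and simulation-based power analysis for binary look data. A synthetic
    multi-method gaze simulator with known ground truth supports validation
    and method studies without any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    tibble,
    dplyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    ggplot2
Config/testthat/edition: 3
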