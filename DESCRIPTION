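Package: urgepfm
Title: Timing-Free Mapping of Urge-Related Brain Activity from Multi-Echo fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing urge and action-suppression experiments with
    multi-echo functional MRI without relying on task timings. Provides a
    synthetic multi-echo phantom and behavioural-trace generator, sparse
    paradigm-free haemodynamic deconvolution of voxelwise R2* changes with
    BIC-based regularisation selection, activation-timeseries event detection
    against a volume-shuffled surrogate null, consensus k-means clustering of
    single-event activation maps, a first-level GLM comparator with parametric
    urge regressors and overlap metrics, and peri-blink behavioural statistics
    (logistic blink models, peri-event averages, curvilinear fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
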