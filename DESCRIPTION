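Package: dfcstates
Title: Dynamic Functional Connectivity State Analysis by Two-Stage Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts recurring functional connectivity states from
    region-of-interest fMRI time series. Builds sliding-window Pearson
    correlation networks with Fisher R-Z variance stabilization, identifies
    states by a two-stage k-means procedure using Manhattan distance with
    exemplar resampling and elbow-rule selection of the cluster number,
    summarizes temporal state dynamics (occupancy, mean dwell time,
    transition counts) with group comparisons, computes graph-theoretical
    integration and segregation indicators on thresholded state networks
    (degree, clustering coefficient, characteristic path length, global and
    local efficiency, modularity, participation coefficient, within-module
    degree z-score), and tests edge-wise group differences with the
    network-based statistic permutation framework and FDR correction. Ships
    a Markov-switching Gaussian simulator that plants connectivity states
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    tidyr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
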