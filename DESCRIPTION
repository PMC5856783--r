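Package: netanova
Title: ANOVA-Style Testing and Subnetwork Identification for Samples of Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nonparametric comparison of groups of labeled networks observed on a
    common node set, as arises when comparing brain connectivity networks between
    subject groups. Provides an analysis-of-variance style test for equality of
    group mean networks based on the graph edit distance, with analytic and
    permutation calibrations of its normalization constant; a combinatorial
    search that identifies the subnetwork expressing the largest group
    differences, with a change-point stopping rule; a link-wise comparator test
    with Benjamini-Hochberg control; utilities for thresholding per-subject
    correlation matrices into networks, a threshold-robustness statistic with a
    resampling null, and a difference network highlighting where group means
    diverge; and a geometric random-network simulator with distance-decaying
    link probabilities for power, type-I-error and identification studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
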