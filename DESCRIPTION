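Package: traitedge
Title: Position of Alien Plant Species in the Functional Trait Space of Local Communities
Version: 0.1.0
Authors@R:
    person("traitedge", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how naturalized and invasive plant species position
    themselves within the multidimensional functional trait space of local
    plant communities. Provides per-plot dispersion (D, the mean distance of a
    community fraction from the native trait-space centroid) and overlap
    (two-sample energy distance, E) statistics in unweighted and cover-weighted
    forms, stratified null models drawing replacement species from habitat
    pools under uniform, frequency and Beals-smoothing weighting schemes,
    deviation (delta-D) and empirical overlap-probability summaries,
    habitat-level paired Wilcoxon tests with Benjamini-Hochberg adjustment and
    effect sizes, and regression trees (CART with 10-fold cross-validation,
    1-SE pruning and surrogate splits) identifying the traits that drive
    deviations. Includes a synthetic vegetation-plot generator emulating
    habitat species pools, invasion-status fractions, life-form stratification
    and percentage covers, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
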