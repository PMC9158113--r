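Package: powerclust
Title: Simulation-Based Statistical Power Analysis for Cluster Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating a priori statistical power of cluster-analysis
    pipelines by Monte-Carlo simulation. Simulates multivariate-normal subgroup
    populations with controlled centroid separation (the multivariate effect
    size Delta, the Euclidean quadrature of per-feature Cohen's d values) and
    covariance structure; runs dimensionality-reduction (none, metric MDS,
    UMAP) and clustering pipelines (k-means, agglomerative, HDBSCAN, fuzzy
    c-means, Gaussian mixtures); and estimates power (probability of declaring
    data "clustered" by the silhouette >= 0.5 rule), cluster-number accuracy,
    and classification accuracy over grids of effect size and sample size.
    Includes the fuzzy silhouette coefficient for membership-weighted
    evaluation of soft partitions, and a matched-data comparison of discrete,
    fuzzy, and mixture-model clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    uwot,
    withr,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
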