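Package: braincca
Title: Cross-Validated Canonical Correlation Analysis of Brain Networks and
    Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multivariate brain-behavior association analysis across
    the lifespan. Builds connection-density networks from streamline counts,
    applies consensus thresholding and node-degree summaries, prepares
    high-dimensional behavior and network feature tables (outlier and
    missingness filtering, z-scoring, nuisance deconfounding, nearest
    positive-definite covariance rotation, PCA), couples the two domains with
    a canonical correlation analysis tuned by a PCA-dimension grid search
    against a hold-out variable (age), cross-validates factors and loadings by
    repeated k-fold resampling, tests them by bootstrap, partitions networks
    into rich-club core and periphery, and characterizes many-to-many domain
    interactions via representational similarity analysis on canonical
    loadings, including an age-isolating model-difference analysis. A
    synthetic-cohort generator provides data with the statistical structure
    the analysis assumes, so every stage is testable without study downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
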