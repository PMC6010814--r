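Package: allophy
Title: Phylogenetic Generalized Least Squares Allometry of Life-History Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetically informed allometric analysis of
    life-history traits. Builds phylogenetic variance-covariance structures
    (Brownian motion, Pagel's lambda, star) from rooted trees, fits log-log
    trait-mass regressions by REML- or ML-based generalized least squares on
    pruned or composite phylogenies, screens covariates, compares clades by
    confidence-interval overlap, and profiles a focal species by its residual
    distance from clade regressions. Ships a synthetic-data generator that
    reproduces the assumed statistical structure (Brownian trait evolution
    with lambda-damped covariance on pure-birth trees) so the whole pipeline
    can be validated by simulation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
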