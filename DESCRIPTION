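Package: geninfo
Title: Comparing Ordinal Outcome Inventories as Measures of a General
    Factor via Marginal Item Response Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing self-report symptom inventories as
    measures of a single general latent factor estimated jointly from
    their pooled ordinal items.  Implements the full isolate-and-analyse
    workflow: pairwise-complete polychoric correlation with sparse-category
    truncation, first-component covariance decomposition and Horn's
    parallel analysis (on pretreatment and change scores), exploratory
    bifactor analysis with bi-geomin rotation, exact normal-ogive
    marginalization of the specific factors to a unidimensional graded
    response model, and Fisher information statistics (point and total
    item/test information, length-averaged information, standard error of
    measurement) with nonparametric bootstrap percentile confidence
    intervals.  A synthetic-cohort generator emulating a psychotherapy
    quality registry provides known-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
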