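Package: boolscreen
Title: Perturbation Screening of Probabilistic Boolean Signal Transduction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and systematic in-silico perturbation analysis of
    Boolean (logical) models of signal transduction. Models are read from
    SBML-qual or a plain-text truth-table dialect and simulated synchronously
    with stochastic external inputs, yielding semi-continuous activity levels
    (0-100). Knockout and overexpression screens across defined extracellular
    environments are scored with a Kolmogorov-Smirnov difference value,
    aggregated into influence scores and rankings, and compared across
    conditions; combinatorial (multi-target) perturbations and fold-difference
    classification support drug-target prioritisation. Includes a random
    Boolean network and synthetic expression-matrix generator, and a
    Z-score/Z-ratio differential-expression stage for concordance checks
    between model predictions and expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
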