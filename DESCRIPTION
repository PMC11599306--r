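Package: hostassay
Title: Bayesian Analysis of Group-Reared Multi-Host Insect Performance Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing common-garden
    rearing assays in which insect larvae from several source populations are
    reared in mixed-brood cultures on a panel of host plants. Provides a
    hierarchical generative model of the assay (population, host,
    population-by-host, culture and brood effects on survival, pupal mass and
    development time), Gibbs and Metropolis-within-Gibbs samplers for
    variance-component mixed models including a binary-logit model with fixed
    residual variance, posterior summaries of link-scale variance shares and
    per-treatment performance predictions, derived posteriors for development
    rate and projected fitness, a simulation framework for quantifying the
    consequences of unmodelled brood structure (pseudoreplication) for bias,
    coverage, false-positive rate and power, and evaluation of the local
    adaptation criteria (local-vs-foreign and home-vs-away) against a map of
    locally abundant host plants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    tools,
    utils,
    jsonlite,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    readxl,
    yaml,
    withr
Config/testthat/edition: 3
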