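Package: hyperurn
Title: Hypernetwork-Based Polya Urn Models of Collective Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates collective decision dynamics as a Polya urn process
    unfolding on a hypernetwork, where hyperedges are social groups carrying
    a norm (a preferred choice) and individuals decide once each by imitating
    a decided group-mate (social influence), conforming to a group norm
    (conformity), or following personal preference. Provides seeded generators
    for uniform and overlapping hypernetworks, a compiled stochastic engine
    with an exact pure-R reference stepper, closed-form mean-field recursions
    for the choice-count distribution and expected market share with their
    convergence value, and ensemble statistics of market share,
    unpredictability (mean pairwise absolute difference across runs) and a
    Gini-type inequality index, together with parameter-sweep experiment
    drivers, tidy accessors and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
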