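Package: procfx
Title: Effectiveness-Enhanced Process Data Mining for Complex Problem-Solving Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the collaborative Balance Beam task as a finite state
    automaton, computes distance-based state and transition effectiveness
    indicators by breadth-first search over the full transition graph, and
    re-represents action sequences in three formats (raw action codes,
    transition effectiveness, state-effectiveness pairs). On top of these
    representations it provides two data-driven feature-extraction methods:
    chi-square selection of n-gram action segments weighted by term
    frequency-inverse sequence frequency with Benjamini-Hochberg correction,
    and K-medoids clustering of dynamic-time-warping distance matrices with
    silhouette and Calinski-Harabasz diagnostics. A seeded softmax-policy
    simulator generates synthetic collaborative action logs with planted
    ability structure so the full pipeline is testable without empirical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
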