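Package: ldsrank
Title: Essential-Protein Ranking from Local Fuzzy Fractal Dimension and
    Subcellular Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks proteins in an undirected protein-protein interaction
    (PPI) network by essentiality. Each node's local fuzzy fractal
    dimension (LFFD) -- the log-log slope of Gaussian-membership fuzzy
    sphere values against topological radius -- captures topology; a
    Bayes-derived subcellular compartment score (SCS) captures biology;
    the LDS score fuses the two as a convex combination. Includes seven
    classical centrality baselines, top-k enrichment and
    confusion-matrix evaluation, deterministic synthetic PPI generators
    with planted essentiality and compartment enrichment, and a
    command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
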