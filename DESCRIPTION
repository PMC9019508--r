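Package: herbrank
Title: Network-Based Herb Screening via GeneRank Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes disease genes by propagating differential-expression
    signal over a protein-protein dependence network with a damped
    PageRank-style fixed-point iteration (GeneRank), then screens a
    herb/ingredient/target compound database for herbs whose ingredients
    preferentially target the top-ranked genes. Includes readers for edge-list
    networks, differential-expression tables and compound databases, packaged
    reference fixtures for the seabuckthorn screen in fish soybean-meal-induced
    enteritis, a direct linear-solve oracle for the iterative ranker, and a
    seeded synthetic-data generator for end-to-end recovery experiments.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
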