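Package: crossmux
Title: Signaling Pathway Crosstalk Inference from Multilayer Network
    Multilink Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a multilayer (multiplex) network from KEGG-style
    signaling pathway definitions (KGML), a protein-protein interaction
    scaffold and a gene regulatory network; counts multilinks (coincident
    signaling/regulatory edge patterns) over edge subsets; assesses their
    over-representation against degree-preserving rewired null ensembles
    with z-scores and empirical p-values; and uses these statistics to
    infer, score and rank crosstalk between ordered pathway pairs.
    Includes overlap-, direct-edge- and shortest-path-based baseline
    methods, deterministic and stochastic ROC/PR benchmarking, and a
    seeded synthetic-data generator with planted crosstalk for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
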