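Package: sdrinventory
Title: Genome-Wide Inventory and Diversification Analysis of Plant
    Short-Chain Dehydrogenases/Reductases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building genome-wide inventories of short-chain
    dehydrogenase/reductase (SDR) proteins from predicted proteomes.
    Implements three-tier profile hidden Markov model classification with
    explicit bit-score cutoffs and a decision tree, similarity-based rescue
    of truncated gene models, single-linkage clustering of orphan families,
    neighbor-joining phylogenies with bootstrap support from p-distances and
    Poisson-corrected distances, and family-by-genome distribution analyses
    (occurrence classes over the green-plant taxon hierarchy, heat-map
    export, principal component analysis with an extreme-individual
    robustness check). A synthetic-proteome generator with controlled
    sequence identity, planted SDR motifs, truncations and decoys makes
    every stage testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
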