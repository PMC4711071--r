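Package: phalign
Title: Partial-Order Multiple Alignment of Collinear Bacteriophage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple whole-genome alignment for sets of functionally
    collinear bacteriophage genomes. Enumerates maximal exact matches with a
    generalized suffix array, builds alignment columns as union-find
    equivalence classes of genome positions, detects non-collinearity
    (rearrangements) as cycles in the column graph, merges and contracts
    columns into gapless alignment vertices with percent-identity
    statistics, exposes anchors and the genome backbone, supports circular
    normalization of start positions, and renders interactive-grade
    Graphviz output. Includes a mosaic-genome simulator with ground truth
    for end-to-end validation and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    tibble,
    utils,
    stats,
    grDevices,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
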