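Package: orthopair
Title: One-to-One Ortholog Mapping and Comparative Analysis of a Pair of
    Prokaryotic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares two annotated prokaryotic genomes by bidirectional
    best-hit ortholog mapping under Karlin-Altschul E-value statistics,
    validates candidate pairs with full-length global alignment, partitions
    the gene complements into shared and unique sets, derives synteny dot
    plots and unique-gene hotspots, and classifies unique coding sequences
    into gene-splitting, gene-deletion, gene-duplication and lateral
    gene-transfer origins. Ships a divergent genome-pair simulator with a
    ground-truth ortholog map and event log so the whole pipeline can be
    exercised and benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
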