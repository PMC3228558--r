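Package: numtsr
Title: Detection, Assembly and Annotation of Nuclear Mitochondrial Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering nuclear mitochondrial sequences
    (NumtS): detects mitochondrial-like fragments (high-scoring pairs) in
    nuclear chromosomes with a seed-and-extend local aligner, assembles
    nearby consistently-oriented fragments into NumtS with merge rules
    aware of the circular mitochondrial genome, computes summary
    statistics and per-base mitochondrial coverage, remaps mitochondrial
    coordinates between reference sequences, and emits UCSC-style BED
    browser tracks. Includes a synthetic-genome simulator with ground
    truth for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
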