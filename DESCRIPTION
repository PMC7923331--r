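Package: calintron
Title: Integron-Associated Group II Introns and Co-Located Mobile Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and characterization of integron recombination sites
    (attC), clusters of attC sites lacking an integrase (CALINs), gene
    cassettes, group II introns (intron-encoded proteins, ribozyme boundaries,
    exon-binding-site pairing, class and integrity calls), IS200/605-family
    insertion sequences with palindromic end hairpins, and leading/lagging
    replication-strand context in bacterial (meta)genomic sequence. Includes a
    maximum base-pairing secondary-structure kernel, conservation statistics
    for sequence-logo data, and a seeded synthetic-landscape generator that
    plants every supported element class with a machine-readable truth ledger
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
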