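Package: chromsplice
Title: A Chromatin Code for Alternative Splicing from ChIP-Seq Cluster
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Relates changes in chromatin-associated ChIP-Seq signals to
    the direction of alternative splicing regulation between two
    conditions. Calls significant ChIP-Seq read clusters against a
    control experiment with a control-normalized Bayesian significance
    model, summarizes each cassette-exon event as relative-enrichment
    z-scores over a fixed scheme of fifteen windows, selects informative
    attributes by combining information gain, correlation-based feature
    selection and a genetic-search wrapper, and learns an alternating
    decision tree that predicts exon inclusion versus skipping.
    Additional components quantify the genomic association between
    cluster sets by block bootstrap, score heptamer enrichment in
    cluster sequences with a one-tailed Fisher test, and generate fully
    synthetic genomes, events, reads and sequences so that every stage
    can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    foreign,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
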