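Package: mirforge
Title: Small-RNA Sequencing miRNA Discovery, isomiR Characterization and
    Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale reimplementation of a teleost small-RNA-seq
    analysis workflow: adapter trimming and read collapsing, Rfam-style
    non-coding-RNA removal, seed-tolerant genome and EST/GSS mapping,
    conserved and novel miRNA calling by hairpin excision and base-pair
    maximization folding, isomiR classification (end shifts, internal
    substitutions, 3' non-template additions) with Drosha/Dicer cleavage-site
    inference, miRNA:miRNA* duplex detection with seed-conservation
    profiling, stem-loop RT-PCR 2^-dCt relative quantification with
    hierarchical clustering, and antisense-complementarity target
    prediction. Ships a synthetic-data generator that plants hairpin
    precursors, isomiR structure and tissue Ct effects with full ground
    truth, so every stage is testable without any sequencing download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    methods,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
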