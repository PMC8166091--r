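Package: repeatDensity
Title: Mononucleotide Repeat Density Around Transcription Start Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links long mononucleotide A/T homopolymer tracts near
    transcription start sites (TSSs) to differential gene expression
    between paired microarray experiments. Detects perfect (intact)
    A and T runs genome-wide, filters them to a length window
    (default 13-27 bp), builds 200-bin TSS-anchored profiles
    (100 bp bins covering 10 kb upstream and 10 kb intragenic),
    assigns run base pairs to bins proportionally, and summarises
    per-gene repeat density in bp/Mbp. Genes are classified as up-,
    down-, or non-regulated per experiment with two-sample Student
    t-tests and intersected across experiments; repeat densities of
    the classes are then compared. A synthetic-data generator plants
    runs and expression effects with a full truth table so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
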