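Package: tnscreen
Title: Simulation and Survival-Index Analysis of Transposon Insertion
    Sequencing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bactericidal-selection transposon insertion
    sequencing (Tn-seq) screens with a mariner-class transposon that
    inserts at TA dinucleotides. Builds a genome coordinate frame of TA
    sites and a tiling catalog of genes and intergenic regions; simulates
    a saturated insertion library through selection, colony bottlenecks
    and barcoded junction-read sequencing with known ground truth;
    processes reads back to per-site counts by barcode demultiplexing and
    exact TA-anchored tag mapping; and computes per-feature normalized
    representation (Dval) and the survival index (SI) with a minimum
    insertion-site filter, replicate log-ratio t-tests and ranked hit
    lists of resistance determinants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
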