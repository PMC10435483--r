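Package: catnet
Title: Nascent Pol II Occupancy Analysis: Antisense Classification,
    Enhancer Calling and Spike-In Differential Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of single-nucleotide nascent transcription
    (NET-seq style) data: UMI duplicate collapse, reverse-transcription
    mispriming and RNA-processing-intermediate artifact filtering, stranded
    single-nucleotide Pol II occupancy track extraction with spike-in
    separation, de novo transcription-unit calling, classification of
    antisense transcription units into convergent (CAT) and divergent (DAT)
    classes, intragenic and extragenic putative-enhancer calling with
    histone-mark support, spike-in median-of-ratios normalization, negative
    binomial differential occupancy testing, promoter-proximal pausing
    matrices, and contact-based enhancer to target-gene assignment.  A
    synthetic-data module generates genomes, reads and occupancy tracks
    with a machine-readable truth table so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    DESeq2
Config/testthat/edition: 3
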