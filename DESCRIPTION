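Package: tccsplice
Title: Isoform Switching Analysis via Transcript Compatibility Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An alignment-free pipeline for detecting isoform switching in bulk
    and single-cell RNA-seq, built on pseudoalignment to transcript equivalence
    classes. Provides a synthetic-data module that generates a toy genome and
    transcriptome (including an SR-family splicing-factor gene whose poison-exon
    cassette toggles between productive and degradation-targeted isoforms) with
    full ground truth; a k-mer pseudoaligner producing transcript compatibility
    count (TCC) matrices with UMI deduplication and quality filters; EM
    transcript quantification with multinomial bootstrap; transcript-level Wald
    tests with Lancaster p-value aggregation to genes and BH FDR control;
    enumeration and likelihood-ratio testing of the five canonical alternative
    splicing event types with length-normalized inclusion levels; and a
    single-cell logistic-regression test that detects isoform switching at
    conserved total gene expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    limma,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
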