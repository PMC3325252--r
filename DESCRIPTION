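Package: bessurvey
Title: Genome Surveys from BAC-End Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide structural surveys based on BAC-end
    sequences (BES): Clarke-Carbon library coverage statistics and
    organellar-contamination estimates, detection of perfect simple
    sequence repeats (SSRs), homology-based annotation and masking of
    known repeat elements, de novo mining of novel repeat families by
    BES self-comparison, GC partitioning of coding and non-coding
    fractions, and comparative paired-end placement with
    microcollinearity block detection.  A deterministic simulator
    generates genomes, BAC clones, end reads and a rearranged related
    reference with full truth tables, so every stage can be exercised
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
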