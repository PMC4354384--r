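Package: rdprep
Title: Read Preprocessing and GC-Corrected Read-Depth Signals for CNV Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prepares short-read sequencing data for read-depth based copy
    number variation (CNV) analysis. Provides quality filtering and masking of
    Illumina FASTQ reads with automatic quality-encoding detection,
    alignment-free removal of PCR duplicates by sorting integer-encoded read
    prefixes and comparing suffixes in numerically encoded chunks, a minimal
    3'-adapter trimmer, post-filtering of SAM alignments (mapping-quality
    threshold, unique-best or seeded random-best resolution of multi-mapped
    reads), and construction of a windowed read-depth signal corrected for
    GC-content bias. A synthetic-data module generates reference sequences,
    error-bearing read libraries with controlled low-quality and duplicate
    fractions, and ideal-aligner SAM files, so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
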