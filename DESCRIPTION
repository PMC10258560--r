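Package: tnseqr
Title: Transposon Insertion Sequencing and Barcoded Lineage Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for mariner-family transposon insertion
    sequencing (Tn-Seq) and random-barcode Tn-Seq (RB-Tn-Seq) readouts:
    junction filtering and trimming of paired-end reads, UMI tagging and
    directional deduplication, barcode extraction and error-correction
    clustering, a lightweight paired-end read placer with SAM import,
    TA-site insertion spectra with orientation inference, Poisson
    local-background peak calling with nearest-gene annotation, gene-level
    negative-binomial differential enrichment between time points, and
    barcode-defined lineage reconstruction with cross-contamination
    detection. A synthetic-data generator produces genomes, barcoded
    insertion populations, and realistic read pairs so every stage can be
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
    purrr,
    Rcpp,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
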