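Package: minicircler
Title: Detection and Characterization of Hybrid Virus/Host DNA Minicircles
    from Paired-End Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-usable pipeline for discovering small circular
    DNA molecules ("minicircles") that join a fragment of a circular
    geminivirus genome, always retaining the rolling-circle replication
    origin, to a fragment of host chromosomal DNA. Covers read quality
    trimming, seed-and-extend split-read alignment to a combined virus+host
    reference, breakpoint junction calling and filtering, targeted recovery
    and greedy overlap assembly of junction-spanning reads, classification of
    scaffolds into hybrid and defective replicons, reconstruction of circular
    molecules with feature annotation (segment lengths, AT content, ORF scan,
    host locus, read-depth copy number), and in-silico validation by
    restriction digestion and inverse PCR. Ships a paired-end read simulator
    that emulates the sequencing design of a geminivirus infection experiment
    so the whole pipeline is testable against a planted truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    IRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
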