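Package: embryoflow
Title: Tissue- and Time-Resolved Embryonic RNA-seq Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for tissue- and time-resolved bulk RNA-seq of sorted
    embryonic cell populations: coverage-stratified PCR-duplicate rate
    estimation and proportional removal (no UMIs required), TPM
    quantification with histone/rRNA exclusion, tissue-specific and
    stably-expressed gene calling with related-tissue exclusion, fuzzy
    k-means clustering of max1-normalized expression profiles, splice-leader
    (SL1/SL2) site classification, novel-intron classification, gene-pair
    orientation and operon regulatory-sharing statistics, transcription-factor
    ChIP-peak enrichment heatmaps, and A-to-G RNA-editing calling. Includes a
    fully seeded synthetic-data generator emulating a 7-tissue x 5-time-point
    sorted-embryo design so every stage can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
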