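Package: darlinker
Title: Linking Chromatin Accessibility Changes to Transcription, Regulatory
    Context, and Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream integration of ATAC-seq and RNA-seq
    experiments in aging and insulin/IGF-like signaling studies. Calls
    differentially accessible regions and differentially expressed genes from
    count tables, joins them at the closest gene into transcriptionally
    relevant differentially accessible regions (trDARs), classifies regions by
    genomic context (promoter, distal non-coding, UTR), tests directional
    cross-condition overlaps, performs chromatin-state, TF-motif, ChIP-peak
    and gene-set enrichment with exact Fisher tests and Benjamini-Hochberg
    correction, and computes bootstrap Kaplan-Meier median lifespan
    statistics. A synthetic-data generator with planted effect structure
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
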