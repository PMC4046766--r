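Package: srnascan
Title: Discovery and Characterization of Bacterial Small RNAs from dRNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A genome-wide small RNA (sRNA) discovery pipeline for bacterial
    differential RNA-Seq (dRNA-Seq) experiments. From strand-specific read-start
    and coverage profiles of a primary-transcript-enriched library and a whole
    small-transcriptome library, the package calls transcription start sites,
    validates them with expectation-maximization-trained sigma-factor promoter
    models, determines transcript 3' ends, detects Rho-independent terminators,
    classifies transcripts by position relative to annotated coding sequences
    (mRNA leader, cis-antisense, antisense UTR, trans-encoded), finds small open
    reading frames with ribosome binding sites, intersects trans-encoded sRNAs
    with structure-conservation windows, and scores functional-class enrichment
    of antisense targets. A fully seeded synthetic-data generator plants ground
    truth (TSS, promoters, terminators, positional classes) so that every stage
    can be benchmarked by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
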