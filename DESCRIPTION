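Package: chiptarget
Title: Transcription-Factor Target-Gene Definition from ChIP-Seq and
    Perturbation Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Defines high-confidence transcription-factor target genes by
    integrating ChIP-Seq binding peaks with H3K4me3 and RNA polymerase II
    chromatin marks and with dual-perturbation (receptor knockdown and
    agonist) expression profiles. Provides genomic interval algebra on
    tidy tables, peak filtering and location categorisation relative to
    gene models, a 16-rule microarray probe-to-gene assignment cascade,
    classification of target genes into ligand-independent repression,
    ligand-switched, and ligand-independent activation response modes,
    consensus DR1/PPRE motif scanning with structural classification, and
    a Monte Carlo test for GWAS-trait enrichment near peaks whose null
    model preserves interval count, sizes, and distance to the closest
    transcription start site. A seeded synthetic-data generator emulates
    every input with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
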