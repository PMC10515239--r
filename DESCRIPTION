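Package: pavscan
Title: Sliding-Window Presence/Absence Variation and Molecular-Clock
    Analysis for Diverged Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects presence/absence variation (PAV) between two genome
    assemblies with an overlapping sliding-window alignment-coverage test,
    classifies PAV genes from transcript-merged CDS overlap with read-support
    validation, enumerates SNPs and small indels on one-to-one syntenic
    blocks, estimates synonymous divergence (Nei-Gojobori 1986) for dating
    whole-genome duplications, dates LTR retrotransposon insertions from
    long-terminal-repeat divergence, profiles genomes from k-mer histograms,
    and filters/thins SNP genotype matrices. Ships a seeded synthetic-genome
    generator that plants species-specific segments, SNPs, indels, duplicated
    blocks and LTR elements with a recorded truth set, so every step of the
    pipeline can be exercised end-to-end against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
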