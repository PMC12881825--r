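Package: methmsp
Title: Methylation-Specific PCR Biomarker Region Discovery from Nanopore Methylation Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate biomarker regions for methylation-specific PCR
    (MSP) from multi-sample per-cytosine methylation calls in bedmethyl format.
    Positions essentially unmethylated in all control samples and
    hypermethylated in disease samples are identified via coverage-gated
    control filtering and boxplot-whisker statistics, dense CpG windows of
    primer length are enumerated and scored by coverage-normalised disease
    methylation, and non-overlapping primer pairs within amplicon length
    bounds are combined into scored MSP regions with optional sequence, GC
    content and gene annotation context. Includes a seeded synthetic methylome
    generator with planted hypermethylated clusters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    optparse,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
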