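Package: metacrispr
Title: Personal Identification from Microbiome CRISPR Spacer Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for metaCRISPR typing: forensic personal
    identification from skin and saliva microbiomes by amplicon sequencing of
    Streptococcus CRISPR spacers. Implements spacer extraction from
    repeat-primer amplicons (quality trimming, primer removal, pair
    reconciliation, primer-dimer artifact classification), abundance-ratio
    denoising into amplicon sequence variants, Bray-Curtis identity calling
    with ROC calibration, qPCR standard-curve fitting and spacer copy-number
    quality control, STR genotype profile comparison, and a synthetic amplicon
    simulator that reproduces the copy-number-dependent reproducibility of the
    assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
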