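Package: txevo
Title: Allele-Specific Expression, Expression Diversity and RNA-Editing
    Signatures in Multiregion Tumour Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for intratumour transcriptomic evolution
    from paired DNA/RNA sequencing of multiregion tumour cohorts.
    Implements copy-number-aware allele-specific expression (ASE) testing
    with an overdispersed beta-binomial model, Fisher combination and
    per-sample FDR classification into copy-number-dependent and
    copy-number-independent ASE; intratumour expression distance (I-TED)
    built on the distance correlation; estimation of the tumour transcript
    fraction from RNA B-allele frequencies under allele-specific copy
    number; post-caller filtering of candidate RNA single-base
    substitutions, strand-aware 192-channel substitution spectra,
    non-negative signature exposure fitting and de novo extraction,
    hairpin-loop detection and APOBEC motif enrichment; and a seeded
    synthetic-cohort generator with known ground truth for end-to-end
    validation.
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
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    rtracklayer,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
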