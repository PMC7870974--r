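Package: sigbind
Title: Transcription-Factor Binding Change Under Mutational Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates 96-class single-base-substitution mutational
    signatures with per-k-mer-change transcription-factor binding
    predictions (QBiC-style score and p-value tables) to estimate, for
    every TF x signature pair, how strongly a mutational process is
    expected to create or destroy binding sites. Computes
    signature-weighted score distributions, Benjamini-Hochberg tail
    thresholds, Gain and Loss Ratios with resampling-based significance,
    promoter mutation spectra from VCF-like calls against a genome and
    annotation, AT/GC position-weight-matrix classification with
    sequence-entropy expectations, and Fisher-exact gene-set enrichment
    of affected TFs. Ships a seeded synthetic-data generator producing
    energy-model score tables, signatures, annotated toy genomes and
    signature-driven mutation cohorts for end-to-end validation.
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
    stats,
    utils,
    methods,
    jsonlite,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
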