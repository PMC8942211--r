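Package: idrconstraint
Title: Mutational Constraint and Functional Feature Enrichment in
    Intrinsically Disordered Protein Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes experimentally annotated intrinsically disordered
    regions (IDRs) of human proteins using residue-level sequence-feature
    annotations and protein-coordinate variant tables. Provides two-sided
    Fisher's exact enrichment of 25 UniProt-style feature classes in
    disordered versus non-annotated residues with Bonferroni correction,
    per-region population and pathogenic variant burden (missense-to-
    synonymous ratios, length and allele-count strata), a median-threshold
    rule that calls each IDR mutation-intolerant or mutation-tolerant per
    mutation type, and permutation feature importance of a bagged
    decision-tree classifier scored by average precision. A seeded synthetic
    proteome generator with planted feature odds ratios and planted
    intolerant regions makes every stage testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
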