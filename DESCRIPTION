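Package: misl
Title: Mutation-Specific Synthetic Lethality Mining from Pan-Cancer Boolean Implications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts mutation-specific synthetic-lethal partner genes from
    primary-tumour mutation, copy-number and expression cohorts by mining
    Boolean implications (HI-HI subset and HI-LO mutual-exclusion
    relationships) between somatic alteration variables, with artificial
    normal augmentation, a passenger-alteration filter based on concordant
    expression change, a mutant-overexpression filter, and permutation-based
    false discovery rate calibration. Also provides the reverse
    biomarker-prediction mode (from a drug's inhibited genes to predictive
    alterations, scored against cell-line pharmacology), validation
    statistics for pooled shRNA dropout screens and mutation-stratified
    essentiality rankings, preranked gene-set enrichment, and pathway
    over-representation with redundancy pruning. A synthetic-cohort
    generator with planted structure makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
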