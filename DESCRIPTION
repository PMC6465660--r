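Package: famseg
Title: Family-Based Rare-Variant Segregation and Pedigree Burden Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rare-variant analysis in multiplex disease families
    from jointly called exome data: post-calling variant preparation
    (multiallelic decomposition with allele trimming, low-complexity-region
    removal, Hardy-Weinberg exact-test exclusion, minor-allele-count
    restriction), a configurable rarity/effect/CADD filter cascade with
    secondary-findings gene exclusion, per-family segregation analysis with
    three-state phenotypes and penetrance exemptions, cross-family
    shared-variant and multi-variant-gene discovery, a pedigree-aware
    gene-dropping permutation burden test, and a synthetic pedigree/exome
    cohort generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    vcfR,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
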