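Package: vitisnp
Title: SNP Array Design, Curation, Kinship and Trait Validation for
    Grapevine Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and exploiting mid-density SNP genotyping
    arrays in grapevine and related Vitis species. Covers candidate-variant
    filtering and quota-based marker selection for array design, sample and
    marker quality control on exported genotype-call matrices, duplicate
    (somatic-variant) detection, parent-offspring and trio inference from
    Mendelian incompatibilities with iterative marker curation, genotype and
    relationship-class principal component analyses, cross-platform genotype
    concordance, chloroplast haplotype assignment with maternal-lineage
    verdicts, and a declarative rule engine validating trait-predictive
    markers. A simulation module generates multi-species panels with planted
    pedigrees, somatic duplicates, plastid haplotypes and trait loci so that
    every stage can be tested against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
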