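Package: imprintr
Title: Parent-of-Origin Allelic Expression Analysis for Placental RNA-Seq Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic imprinting from bulk RNA-seq of placental samples
    with matched parental genotypes. Implements the full analysis cascade:
    candidate gene and SNP filtering (expression, minor allele frequency,
    Hardy-Weinberg equilibrium, exonic location, read coverage), trio/duo-based
    assignment of parental origin to expressed alleles, gene-level exact
    binomial testing of maternal versus paternal read proportions with
    Bonferroni correction, and three-way classification of loci as imprinted,
    parentally biased, or biallelic. Ships a synthetic trio-cohort generator
    (Hardy-Weinberg genotypes, Mendelian transmission, parent-of-origin read
    proportions, maternal-cell contamination, sequencing error) with a
    ground-truth ledger so every stage is testable without access to raw
    patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
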