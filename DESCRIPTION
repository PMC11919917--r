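Package: pgtdup
Title: Preimplantation Genetic Testing for Tandem Microduplications by
    SNP Linkage and Binned Copy-Number Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linkage-analysis based preimplantation genetic
    testing (PGT-M) of a tandem microduplication together with
    low-coverage binned copy-number analysis (PGT-A). Selects informative
    SNPs flanking and inside a duplication, phases the carrier parent's
    high-risk and low-risk haplotypes through an affected proband,
    classifies embryos by per-SNP haplotype votes, and calls copy-number
    gains and losses from binned read counts with circular binary
    segmentation at dual resolution. Includes a synthetic pedigree and
    embryo generator with whole-genome-amplification allele dropout and
    shallow-coverage noise so the whole workflow is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
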