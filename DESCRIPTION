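Package: recmapr
Title: Mapping Recessive Disease Variants by Autozygosity in Livestock Pedigrees
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for mapping monogenic autosomal recessive
    diseases in inbred animal populations, built around the classical design of a
    handful of affected, autozygous individuals and a small control panel typed on a
    SNP array. Provides marker quality control, allelic case-control association with
    max-T permutation genome-wide significance and genomic-inflation estimation,
    run-of-homozygosity detection and shared-autozygosity critical-interval mapping,
    a recessive segregation filter cascade over multi-sample variant calls with
    breed-privacy and cohort-concordance scoring, transcript-aware cDNA/protein
    coordinate arithmetic with coding-effect classification, and an exact
    allele-balance test for allele-specific expression. A gene-drop pedigree
    simulator with known ground truth generates array genotypes, whole-genome variant
    tables and allele-count data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    vcfR,
    Biostrings,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
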