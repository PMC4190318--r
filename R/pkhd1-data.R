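#' Published coding-region variants of the equine PKHD1 critical interval
#'
#' The sixteen non-synonymous variants reported on horse chromosome 20 within
#' the 952-kb congenital-hepatic-fibrosis critical interval, relative to the
#' EquCab2 reference assembly: genomic position, reference and variant
#' alleles (genomic strand), gene, and the published cDNA and protein
#' substitution for the fourteen PKHD1 missense variants. The two EFHC1
#' records are single-base insertions attributed to frame-shift errors in the
#' reference assembly and carry the assembly-error flag instead of an HGVS
#' substitution. PKHD1 is transcribed from the minus strand, so genomic
#' positions ascend while cDNA coordinates descend.
#'
#' @return tibble: chrom, pos, ref, alt, gene, cdna, protein, assembly_error
#' @export
pkhd1_coding_variants <- function() {
  tibble::tribble(
    ~pos,     ~ref, ~alt, ~gene,   ~cdna,        ~protein,
    49398500, "C",  "T",  "PKHD1", "c.10796G>A", "p.R3599H",
    49398692, "A",  "C",  "PKHD1", "c.10604T>G", "p.L3535R",
    49597760, "A",  "T",  "PKHD1", "c.6845T>A",  "p.I2282N",
    49630834, "G",  "A",  "PKHD1", "c.6112C>T",  "p.H2038Y",
    49630951, "T",  "C",  "PKHD1", "c.5995A>G",  "p.K1999E",
    49709730, "C",  "A",  "PKHD1", "c.4462T>G",  "p.A1488S",
    49709928, "C",  "T",  "PKHD1", "c.4264G>A",  "p.D1422N",
    49710356, "G",  "C",  "PKHD1", "c.3836C>G",  "p.A1279G",
    49710359, "C",  "T",  "PKHD1", "c.3833G>A",  "p.R1278Q",
    49710363, "A",  "G",  "PKHD1", "c.3829T>C",  "p.S1277P",
    49710468, "C",  "T",  "PKHD1", "c.3724G>A",  "p.E1242K",
    49740355, "C",  "T",  "PKHD1", "c.1811G>A",  "p.R604Q",
    49741254, "C",  "T",  "PKHD1", "c.1670G>A",  "p.R557Q",
    49766468, "T",  "C",  "PKHD1", "c.317A>G",   "p.E106G",
    50077556, "G",  "GC", "EFHC1", NA,           NA,
    50077559, "G",  "GC", "EFHC1", NA,           NA
  ) |>
    dplyr::mutate(chrom = "20", .before = 1) |>
    dplyr::mutate(assembly_error = .data$gene == "EFHC1")
}

#' Published cohort genotype counts for the two top PKHD1 variants
#'
#' Genotype distributions, by cohort, for the missense variant c.6845T>A
#' (g.49,597,760A>T, genotype classes ref/ref, ref/alt, alt/alt) and the
#' intronic candidate variant g.49,552,834C>T from the large genotyping
#' cohorts: affected foals, breed controls at least five years old, and
#' unsorted population controls (phenotype treated as unknown for
#' concordance purposes, since one homozygote was slaughtered before
#' phenotyping age).
#'
#' @return tibble: variant, cohort, phenotype, n_hom_ref, n_het, n_hom_alt
#' @export
pkhd1_cohort_genotypes <- function() {
  tibble::tribble(
    ~variant,       ~cohort,                 ~phenotype,   ~n_hom_ref, ~n_het, ~n_hom_alt,
    "c.6845T>A",    "affected_foals",        "affected",    0L,  1L, 19L,
    "c.6845T>A",    "breed_controls_5y",     "unaffected",  135L, 35L, 3L,
    "c.6845T>A",    "population_controls",   "unknown",     1304L, 259L, 1L,
    "g.49552834C>T", "affected_foals",       "affected",    0L,  3L, 17L,
    "g.49552834C>T", "breed_controls_5y",    "unaffected",  142L, 30L, 1L,
    "g.49552834C>T", "population_controls",  "unknown",     1346L, 217L, 1L
  ) |>
    dplyr::mutate(variant_id = .data$variant, .before = 1)
}
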