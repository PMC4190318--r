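test_that("filter cascade reproduces the configured class structure", {
  cfg <- sim_config(seed = 17)
  st <- simulate_study(cfg)
  wgs <- simulate_wgs_variants(cfg, st)
  b <- st$truth$shared_block
  fm <- wgs$panel$sample_id[wgs$panel$role == "control"]
  res <- segregation_filter(wgs$variants, "wgs_case", "wgs_carrier", fm,
                            region = list(chrom = b$chrom, start = b$start_bp,
                                          end = b$end_bp))
  wc <- cfg$wgs_counts
  expect_equal(res$report$stage,
               c("region", "case_hom", "carrier_het", "control_hom"))
  expect_true(all(diff(c(res$report$n_input[1], res$report$n_surviving)) <= 0))
  expect_equal(res$report$n_surviving,
               c(wc$case_hom_only + wc$carrier_het_control_hom + wc$segregating,
                 wc$case_hom_only + wc$carrier_het_control_hom + wc$segregating,
                 wc$carrier_het_control_hom + wc$segregating,
                 wc$segregating))
  final <- breed_private(res$candidates, wgs$panel, "FM")
  expect_equal(nrow(final), 1L)
  expect_equal(final$variant_id, wgs$causal_variant_id)
})

test_that("an adversarial control homozygote costs the causal variant", {
  cfg <- sim_config(seed = 17)
  st <- simulate_study(cfg)
  wgs <- simulate_wgs_variants(cfg, st, adversarial_control_hom = TRUE)
  b <- st$truth$shared_block
  fm <- wgs$panel$sample_id[wgs$panel$role == "control"]
  res <- segregation_filter(wgs$variants, "wgs_case", "wgs_carrier", fm,
                            region = sprintf("%s:%d-%d", b$chrom, b$start_bp,
                                             b$end_bp))
  expect_false(wgs$causal_variant_id %in% res$candidates$variant_id)
})

test_that("cascade rule details: empty input, hom control, missing calls", {
  v <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4"),
    chrom = "20", pos = c(10L, 20L, 30L, 40L),
    ref = "A", alt = "G",
    case = c(2L, 2L, 2L, NA),
    carr = c(1L, 1L, 1L, 1L),
    c1 = c(0L, 2L, NA, 0L),
    c2 = c(1L, 0L, 0L, 0L))
  reg <- list(chrom = "20", start = 1, end = 100)
  res <- segregation_filter(v, "case", "carr", c("c1", "c2"), reg)
  # v2 removed (hom-alt control); v3 kept (missing control is no evidence);
  # v4 kept but flagged (missing case call)
  expect_setequal(res$candidates$variant_id, c("v1", "v3", "v4"))
  expect_equal(res$flagged, "v4")

  empty <- segregation_filter(v[0, ], "case", "carr", c("c1", "c2"), reg)
  expect_true(all(empty$report$n_surviving == 0L))
  expect_error(segregation_filter(v, "case", "case", "c1", reg), "differ")
})

test_that("breed privacy keeps only variants confined to the target breed", {
  v <- tibble::tibble(
    variant_id = c("keep", "drop_het", "drop_hom", "absent"),
    chrom = "20", pos = 1:4 * 10L, ref = "A", alt = "G",
    fm1 = c(2L, 2L, 2L, 0L), fm2 = c(1L, 0L, 0L, 0L),
    ob1 = c(0L, 1L, 2L, 0L))
  samples <- tibble::tibble(sample_id = c("fm1", "fm2", "ob1"),
                            phenotype = "unaffected",
                            breed = c("FM", "FM", "WB"),
                            role = "control")
  out <- breed_private(v, samples, "FM")
  expect_setequal(out$variant_id, c("keep", "absent"))
  samples$breed[3] <- NA
  expect_error(breed_private(v, samples, "FM"), "breed label")
  expect_equal(nrow(breed_private(v[0, ], samples, "FM")), 0L)
})

test_that("recessive concordance matches the published cohort counts", {
  counts <- pkhd1_cohort_genotypes()
  res <- genotype_concordance(
    dplyr::filter(counts, .data$phenotype != "unknown"))
  aff <- dplyr::filter(res, .data$phenotype == "affected")
  # one discordant affected animal for the missense variant, three for the
  # intronic variant
  expect_equal(aff$n_discordant[aff$variant == "c.6845T>A"], 1L)
  expect_equal(aff$n_discordant[aff$variant == "g.49552834C>T"], 3L)
  # aged unaffected cohort: homozygotes are the discordant animals
  ctl <- dplyr::filter(res, .data$cohort == "breed_controls_5y")
  expect_equal(ctl$n_discordant[ctl$variant == "c.6845T>A"], 3L)
  expect_equal(ctl$n_discordant[ctl$variant == "g.49552834C>T"], 1L)
})

test_that("concordance is symmetric under consistent genotype relabeling", {
  tab <- tibble::tibble(variant_id = "v", cohort = c("aff", "ctl"),
                        phenotype = c("affected", "unaffected"),
                        n_hom_ref = c(1L, 20L), n_het = c(2L, 5L),
                        n_hom_alt = c(17L, 2L))
  res <- genotype_concordance(tab)
  expect_equal(res$n_discordant, c(3L, 2L))
  # fully concordant cohorts
  perfect <- tibble::tibble(variant_id = "v", cohort = "aff",
                            phenotype = "affected",
                            n_hom_ref = 0L, n_het = 0L, n_hom_alt = 12L)
  expect_equal(genotype_concordance(perfect)$n_discordant, 0L)
  expect_error(genotype_concordance(dplyr::mutate(perfect, n_het = -1L)),
               "non-negative")
})
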