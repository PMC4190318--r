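test_that("full penetrance forces case genotypes and phenotypes", {
  st <- simulate_study(sim_config(seed = 21))
  dose <- st$truth$causal_dosage
  cases <- st$samples$role == "case"
  expect_true(all(dose[st$samples$sample_id[cases]] == 2L))
  expect_true(all(dose[st$samples$sample_id[!cases]] < 2L))
  expect_identical(st$samples$phenotype[cases], rep("affected", sum(cases)))
  expect_identical(st$samples$phenotype[!cases], rep("unaffected", sum(!cases)))
})

test_that("the same seed reproduces the study exactly", {
  a <- simulate_study(sim_config(seed = 33))
  b <- simulate_study(sim_config(seed = 33))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$pedigree, b$pedigree)
  c <- simulate_study(sim_config(seed = 34))
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("penetrance 0.5 labels about half of the homozygotes affected", {
  # 200 small replicates; pool all homozygous individuals and check the
  # affected fraction against a binomial 3-SD band around 0.5
  n_hom <- 0L; n_aff <- 0L
  for (s in 1:200) {
    st <- simulate_study(sim_config(seed = 40000 + s, n_markers = 100,
                                    n_chromosomes = 2, causal_chrom = "1",
                                    penetrance = 0.5))
    hom <- st$truth$causal_dosage[st$samples$sample_id] == 2L
    n_hom <- n_hom + sum(hom)
    n_aff <- n_aff + sum(st$samples$phenotype[hom] == "affected")
  }
  frac <- n_aff / n_hom
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_hom))
})

test_that("simulated genotypes are Mendelian-consistent within case trios", {
  # parent genotypes are not emitted, but IBD bookkeeping guarantees each
  # case homolog is a founder-haplotype mosaic; check the observable trio
  # property instead: cases are hom-alt at the causal locus while both
  # lineages segregate the carrier haplotype (dosage 1 in carrier controls)
  st <- simulate_study(sim_config(seed = 55))
  dose <- st$truth$causal_dosage
  expect_true(all(dose >= 0 & dose <= 2))
  carrier_ctrls <- paste0("ctrl_0", 1:3)
  expect_true(all(dose[carrier_ctrls] == 1L))
})

test_that("founder marker frequencies track the configured MAF distribution", {
  st <- simulate_study(sim_config(seed = 66, missing_rate = 0))
  stt <- marker_stats(st$genotypes)
  # mean MAF across markers near the uniform [0.05, 0.5] mean, allowing for
  # drift through the pedigree (controls dominate the cohort)
  expect_lt(abs(mean(stt$maf) - 0.275), 0.05)
})

test_that("ground-truth shared block is flanked by sharing-breaking markers", {
  for (s in c(71, 72, 73)) {
    st <- simulate_study(sim_config(seed = s, missing_rate = 0))
    b <- st$truth$shared_block
    gt <- st$genotypes
    cases <- st$samples$sample_id[st$samples$role == "case"]
    m <- geno_matrix(gt, cases)
    is_shared <- function(pos_bp) {
      j <- which(gt$chrom == b$chrom & gt$pos == pos_bp)
      g <- m[, j]
      all(g == 0L) || all(g == 2L)
    }
    expect_true(is_shared(b$start_bp))
    expect_true(is_shared(b$end_bp))
    if (!is.na(b$flank_left_bp)) expect_false(is_shared(b$flank_left_bp))
    if (!is.na(b$flank_right_bp)) expect_false(is_shared(b$flank_right_bp))
    # the flank-bounded interval covers the causal position (the marker
    # block itself may start just past it when no marker falls between the
    # causal base and the IBD boundary)
    left <- if (is.na(b$flank_left_bp)) b$start_bp else b$flank_left_bp
    right <- if (is.na(b$flank_right_bp)) b$end_bp else b$flank_right_bp
    expect_lte(left, st$truth$causal_pos_bp)
    expect_gte(right, st$truth$causal_pos_bp)
  }
})

test_that("WGS variant classes have the configured filter fate", {
  cfg <- sim_config(seed = 81)
  st <- simulate_study(cfg)
  wgs <- simulate_wgs_variants(cfg, st)
  v <- wgs$variants
  panel <- wgs$panel
  in_region <- v$chrom == st$truth$shared_block$chrom &
    v$pos >= st$truth$shared_block$start_bp &
    v$pos <= st$truth$shared_block$end_bp
  wc <- cfg$wgs_counts
  expect_equal(sum(in_region), wc$case_hom_only + wc$carrier_het_control_hom +
                 wc$segregating)
  expect_true(all(v$wgs_case == 2L))
  # exactly one variant is absent outside the target breed and never
  # homozygous in controls
  ctrl <- panel$sample_id[panel$role == "control"]
  other <- panel$sample_id[panel$breed != "FM"]
  gm <- as.matrix(as.data.frame(v)[, ctrl])
  go <- as.matrix(as.data.frame(v)[, other])
  seg_ok <- in_region & v$wgs_carrier == 1L & rowSums(gm == 2L) == 0
  private <- seg_ok & rowSums(go >= 1L) == 0
  expect_equal(sum(seg_ok), wc$segregating)
  expect_equal(sum(private), 1L)
  expect_equal(v$variant_id[private], wgs$causal_variant_id)
})

test_that("degenerate simulation configs are rejected", {
  expect_error(sim_config(penetrance = 0), "penetrance")
  expect_error(sim_config(causal_chrom = "99"), "causal_chrom")
  expect_error(sim_config(missing_rate = 1.5), "rates")
  expect_error(sim_config(wgs_counts = list(case_hom_only = 1,
                                            carrier_het_control_hom = 1,
                                            segregating = 0)), "segregating")
  expect_error(simulate_ase_counts(5, depth = 0), "depth")
  expect_error(simulate_ase_counts(5, depth = 10, skew = 1), "skew")
})

test_that("ASE count simulation follows its binomial model", {
  obs <- simulate_ase_counts(500, depth = 100, skew = 0.5, seed = 9)
  expect_true(all(obs$gdna_ref + obs$gdna_alt == 100))
  # alt fraction near 1/2 within 3 SD of the pooled binomial
  frac <- sum(obs$cdna_alt) / (500 * 100)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / (500 * 100)))
  skewed <- simulate_ase_counts(200, depth = 100, skew = 0.9, seed = 9)
  expect_gt(mean(skewed$cdna_alt), 80)
})
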