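test_that("QC removes markers in fixed rule order with correct attribution", {
  # 17 samples, planted failures: 3 call-rate, 4 MAF, rest clean
  set.seed(1)
  n <- 17
  calls <- matrix(rbinom(n * 100, 2, 0.3), nrow = n)
  calls[1:3, 1:3] <- NA          # 3/17 missing = 82% call rate -> removed
  calls[, 4:7] <- 0L             # monomorphic -> MAF 0
  calls[, 4:7][1, ] <- 1L        # MAF 1/34 < 0.05
  calls[1, 8] <- NA              # 16/17 = 94% call rate, retained
  gt <- toy_geno(calls)
  res <- qc_filter(gt, qc_thresholds())
  expect_equal(res$report$reason, c("call_rate", "maf", "hwe"))
  expect_equal(res$report$n_removed[1:2], c(3L, 4L))
  expect_equal(res$m, nrow(gt) - sum(res$report$n_removed))
  expect_true("m008" %in% res$genotypes$marker_id)
  expect_setequal(res$removed$reason[res$removed$marker_id %in%
                                     c("m004", "m005")], "maf")
  # a marker failing both call rate and MAF is attributed to call rate
  expect_setequal(res$removed$reason[res$removed$marker_id %in%
                                     c("m001", "m002", "m003")], "call_rate")
})

test_that("QC that removes everything warns and returns an empty table", {
  calls <- matrix(0L, 5, 3)
  gt <- toy_geno(calls)
  expect_warning(res <- qc_filter(gt), "all markers removed")
  expect_equal(res$m, 0L)
})

test_that("HWE exact p matches a Monte-Carlo allele-shuffling oracle", {
  set.seed(42)
  cases <- list(c(10L, 0L, 10L), c(3L, 6L, 3L), c(5L, 10L, 5L), c(2L, 1L, 7L))
  for (cs in cases) {
    p_impl <- hwe_exact_p(cs[1], cs[2], cs[3])
    p_mc <- oracle_hwe_mc(cs[1], cs[2], cs[3])
    expect_lt(abs(p_impl - p_mc), 0.02)
  }
  # extreme heterozygote deficit is less probable than a balanced split
  expect_gte(hwe_exact_p(3, 6, 3), hwe_exact_p(6, 0, 6))
})

test_that("HWE conventions: monomorphic markers and invalid counts", {
  expect_equal(hwe_exact_p(17, 0, 0), 1)
  expect_equal(hwe_exact_p(0, 0, 9), 1)
  expect_error(hwe_exact_p(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_p(0, 0, 0), "at least one")
})

test_that("allelic chi-square reproduces complete separation and the null", {
  # complete separation in the 5-case/12-control design: 10 vs 0 alt alleles
  sep <- allelic_test(10, 0, 0, 24)
  expect_equal(sep$chi2, 34)
  expect_equal(signif(sep$p_raw, 2), 5.5e-9)
  null <- allelic_test(5, 5, 12, 12)
  expect_equal(null$chi2, 0)
  expect_equal(null$p_raw, 1)
  expect_error(allelic_test(-1, 2, 3, 4), "non-negative")
})

test_that("allelic chi-square agrees with independent textbook formula", {
  tabs <- list(c(7, 3, 6, 18), c(10, 14, 3, 21), c(1, 9, 9, 1))
  for (t4 in tabs) {
    got <- allelic_test(t4[1], t4[2], t4[3], t4[4])
    expect_equal(got$chi2, oracle_chi2(t4[1], t4[2], t4[3], t4[4]))
    ct <- suppressWarnings(stats::chisq.test(
      matrix(t4, 2, 2, byrow = TRUE), correct = FALSE))
    expect_equal(got$p_raw, ct$p.value)
  }
})

test_that("chi-square is bounded by total allele count, equality at separation", {
  set.seed(3)
  for (i in 1:50) {
    x <- rmultinom(1, 40, rep(0.25, 4))
    n <- sum(x)
    chi2 <- allelic_test(x[1], x[2], x[3], x[4])$chi2
    expect_lte(chi2, n + 1e-9)
  }
  expect_equal(allelic_test(8, 0, 0, 20)$chi2, 28)
})

test_that("orientation invariance: swapping allele labels changes nothing", {
  st <- simulate_null_genotypes(n_samples = 12, n_markers = 200, seed = 4)
  scan1 <- assoc_scan(st$genotypes, st$samples)
  gt2 <- st$genotypes
  m <- geno_matrix(gt2)
  m[, 1:50] <- 2L - m[, 1:50]
  gt2[, sample_cols(gt2)] <- tibble::as_tibble(t(m), .name_repair = "minimal")
  scan2 <- assoc_scan(gt2, st$samples)
  expect_equal(scan1$chi2, scan2$chi2)
  expect_equal(scan1$p_raw, scan2$p_raw)
})

test_that("genomic inflation is the median chi-square over its null median", {
  expect_equal(genomic_inflation(rep(0.4549364, 5)), 1, tolerance = 1e-4)
  expect_equal(genomic_inflation(rep(0.4549364 * 1.33, 101)), 1.33,
               tolerance = 1e-4)
  set.seed(7)
  expect_lt(abs(genomic_inflation(rchisq(10000, 1)) - 1), 0.05)
  expect_error(genomic_inflation(numeric(0)), "no finite")
})

test_that("Bonferroni correction caps at 1", {
  p <- allelic_test(10, 0, 0, 24)$p_raw
  expect_equal(signif(bonferroni_p(p, 38394), 2), 0.00021)
  expect_equal(bonferroni_p(1, 10), 1)
  expect_equal(bonferroni_p(0.001, 50), 0.05)
})

test_that("scan results carry broom-style tidy and glance methods", {
  st <- simulate_null_genotypes(n_samples = 10, n_markers = 50, seed = 8)
  scan <- assoc_scan(st$genotypes, st$samples)
  td <- tidy(scan)
  expect_s3_class(td, "tbl_df")
  expect_false(is.unsorted(td$p_raw))
  gl <- glance(scan)
  expect_equal(gl$m, 50L)
  expect_equal(gl$top_marker, td$marker_id[1])
})
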