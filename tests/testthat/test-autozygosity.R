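test_that("ROH detection applies all three thresholds exactly", {
  # 30 homozygous calls + 1 embedded het spanning ~600 kb
  g <- rep(2L, 31); g[15] <- 1L
  calls <- matrix(g, nrow = 1)
  gt <- toy_geno(calls, pos = seq(1e6, by = 20000, length.out = 31))
  seg <- detect_roh(gt, "s01")
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 30L)
  expect_equal(seg$n_het_inside, 1L)
  expect_gte(seg$end_bp - seg$start_bp, 500000)

  # 24 homozygous calls over 600 kb: fails min_snps = 25
  calls24 <- matrix(rep(0L, 24), nrow = 1)
  gt24 <- toy_geno(calls24, pos = seq(1e6, by = 26000, length.out = 24))
  expect_equal(nrow(detect_roh(gt24, "s01")), 0L)

  # 30 homozygous calls over only 290 kb: fails min_length
  gt_short <- toy_geno(matrix(rep(2L, 30), nrow = 1),
                       pos = seq(1e6, by = 10000, length.out = 30))
  expect_equal(nrow(detect_roh(gt_short, "s01")), 0L)

  # an all-heterozygous sample has no runs
  gt_het <- toy_geno(matrix(rep(1L, 40), nrow = 1))
  expect_equal(nrow(detect_roh(gt_het, "s01")), 0L)
})

test_that("missing calls neither break runs nor count toward totals", {
  g <- rep(2L, 30); g[c(10, 20)] <- NA
  gt <- toy_geno(matrix(g, nrow = 1), pos = seq(1e6, by = 25000, length.out = 30))
  seg <- detect_roh(gt, "s01")
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 28L)
  expect_equal(seg$n_het_inside, 0L)
})

test_that("two heterozygotes split a run under max_het = 1", {
  g <- c(rep(2L, 30), 1L, rep(2L, 5), 1L, rep(2L, 30))
  gt <- toy_geno(matrix(g, nrow = 1), pos = seq(1e6, by = 25000,
                                                length.out = length(g)))
  seg <- detect_roh(gt, "s01")
  # each maximal window holds one het; the two long halves qualify
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$n_het_inside <= 1L))
  expect_true(all(seg$n_snps >= 25L))
})

test_that("every returned segment satisfies the thresholds (property)", {
  for (s in 1:5) {
    st <- simulate_study(sim_config(seed = 300 + s))
    p <- roh_params()
    segs <- detect_roh(st$genotypes, "case_01", p)
    expect_true(all(segs$n_snps >= p$min_snps))
    expect_true(all(segs$n_het_inside <= p$max_het))
    expect_true(all(segs$end_bp - segs$start_bp >= p$min_length_kb * 1000))
  }
})

test_that("shared segment on the published block structure returns 31 markers", {
  gt <- shared_block_fixture(n_block = 31)
  cases <- sample_cols(gt)
  ci <- shared_autozygous_segment(gt, cases)
  expect_equal(nrow(ci), 1L)
  expect_equal(ci$n_shared_snps, 31L)
  # bounds are the flanking heterozygous markers themselves
  expect_equal(ci$left_bound_bp, gt$pos[1])
  expect_equal(ci$right_bound_bp, gt$pos[nrow(gt)])
})

test_that("a mid-segment double heterozygote splits the block", {
  gt <- shared_block_fixture(n_block = 62)
  # case 3 heterozygous at two interior markers -> its ROH splits there
  gt[[sample_cols(gt)[3]]][c(30, 32)] <- 1L
  ci <- shared_autozygous_segment(gt, sample_cols(gt))
  expect_equal(nrow(ci), 1L)
  expect_lt(ci$n_shared_snps, 62L)
  # the returned half excludes both het markers
  expect_true(ci$first_marker %in% gt$marker_id[33:63] ||
              ci$last_marker %in% gt$marker_id[2:29])
})

test_that("opposite homozygotes break allele sharing", {
  gt <- shared_block_fixture(n_block = 62)
  g <- gt[[sample_cols(gt)[2]]]
  g[31] <- 0L   # hom for the other allele mid-block
  gt[[sample_cols(gt)[2]]] <- g
  ci <- shared_autozygous_segment(gt, sample_cols(gt))
  expect_equal(nrow(ci), 1L)
  expect_lt(ci$n_shared_snps, 62L)
  expect_true(gt$marker_id[31] < ci$first_marker ||
              gt$marker_id[31] > ci$last_marker)
})

test_that("shared segment is independent of case ordering and within case ROH", {
  st <- simulate_study(sim_config(seed = 91, n_markers = 38394))
  cases <- st$samples$sample_id[st$samples$role == "case"]
  a <- shared_autozygous_segment(st$genotypes, cases)
  b <- shared_autozygous_segment(st$genotypes, rev(cases))
  expect_identical(a, b)
  expect_equal(nrow(a), 1L)
  # the shared run (between its anchor markers) lies inside a ROH of every case
  p1 <- st$genotypes$pos[match(a$first_marker, st$genotypes$marker_id)]
  p2 <- st$genotypes$pos[match(a$last_marker, st$genotypes$marker_id)]
  for (cs in cases) {
    roh <- detect_roh(st$genotypes, cs)
    expect_true(any(roh$chrom == a$chrom & roh$start_bp <= p1 &
                    roh$end_bp >= p2))
  }
})

test_that("interval arithmetic matches the printed flanking coordinates", {
  il <- interval_length(49164218, 50115936)
  expect_equal(il$length_bp, 951718)
  expect_equal(il$length_kb, 952)
  expect_equal(interval_length(1000, 2000)$length_bp, 1000)
  expect_equal(interval_length(1000, 2000)$length_kb, 1)
  # half-up rounding at the .5 boundary
  expect_equal(interval_length(0, 1500)$length_kb, 2)
  expect_error(interval_length(200, 100), "exceed")
})

test_that("BED export converts to 0-based half-open coordinates", {
  seg <- tibble::tibble(sample_id = "s1", chrom = "20",
                        start_bp = 101L, end_bp = 200L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(seg, path)
  expect_equal(readLines(path), "20\t100\t200\ts1")
})
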