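# fixture builders shared across test files

# a small genotype tibble: calls is samples x markers with values 0/1/2/NA
toy_geno <- function(calls, pos = NULL, chrom = "1", sample_ids = NULL) {
  n_mark <- ncol(calls)
  sample_ids <- sample_ids %||% sprintf("s%02d", seq_len(nrow(calls)))
  rownames(calls) <- sample_ids
  map <- tibble::tibble(
    marker_id = sprintf("m%03d", seq_len(n_mark)),
    chrom = rep(chrom, length.out = n_mark),
    pos = pos %||% seq(1e6, by = 1e5, length.out = n_mark),
    a1 = rep("A", n_mark), a2 = rep("G", n_mark)
  )
  as_geno_table(calls, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# five cases identical-homozygous over `n_block` consecutive markers flanked
# by a marker heterozygous in one case on each side; marker spacing chosen so
# the block spans > 500 kb
shared_block_fixture <- function(n_block = 31, n_cases = 5, spacing = 30000) {
  n_mark <- n_block + 2
  calls <- matrix(2L, n_cases, n_mark)
  calls[1, 1] <- 1L
  calls[2, n_mark] <- 1L
  toy_geno(calls, pos = seq(1e6, by = spacing, length.out = n_mark),
           chrom = "20")
}

# a two-exon toy transcript on either strand; exon1 100-149, exon2 200-259
toy_transcript <- function(strand = "+") {
  transcript_model(
    tibble::tibble(start = c(100L, 200L), end = c(149L, 259L)),
    strand = strand
  )
}

# minimal VCF text fixture written to a temp file
write_vcf_fixture <- function(path, extra_rows = character()) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sampleA", "sampleB"), collapse = "\t"),
    "20\t100\tv1\tA\tG\t.\t.\t.\tGT\t0/1\t1|1",
    "20\t200\tv2\tC\tT\t.\t.\t.\tGT\t0/0\t./.",
    "20\t300\tv3\tG\tA\t.\t.\t.\tGT\t1/0\t0/0",
    extra_rows
  )
  writeLines(lines, path)
  path
}

# independent-oracle chi-square for a 2x2 allele table (textbook formula,
# expected counts route -- distinct from the implementation's determinant form)
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  n <- sum(obs)
  exp_ <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - exp_)^2 / exp_)
}

# Monte-Carlo oracle for the HWE exact test: shuffle the 2n alleles into n
# diploids and tabulate the heterozygote-count distribution
oracle_hwe_mc <- function(n_hom_ref, n_het, n_hom_alt, n_rep = 40000) {
  n <- n_hom_ref + n_het + n_hom_alt
  alleles <- rep(c(0L, 1L), c(2L * n_hom_ref + n_het, 2L * n_hom_alt + n_het))
  hets <- replicate(n_rep, {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  })
  emp <- table(hets) / n_rep
  p_obs <- emp[as.character(n_het)]
  if (is.na(p_obs)) p_obs <- 0
  sum(emp[emp <= p_obs + 1e-9])
}

# exhaustive max-T permutation oracle over all case labelings
oracle_maxt <- function(gt, is_case_obs) {
  m <- geno_matrix(gt)
  n <- nrow(m); n_case <- sum(is_case_obs)
  chi_for <- function(case_idx) {
    is_case <- seq_len(n) %in% case_idx
    mm <- m; mm[is.na(mm)] <- 0L
    ok <- !is.na(m)
    ca <- colSums(mm[is_case, , drop = FALSE])
    cn <- colSums(ok[is_case, , drop = FALSE])
    oa <- colSums(mm[!is_case, , drop = FALSE])
    on_ <- colSums(ok[!is_case, , drop = FALSE])
    r1 <- 2 * cn; r2 <- 2 * on_
    apply(cbind(ca, r1 - ca, oa, r2 - oa), 1, function(x) {
      tab <- matrix(x, 2, 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(0)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
    })
  }
  obs <- chi_for(which(is_case_obs))
  combos <- utils::combn(n, n_case)
  maxima <- apply(combos, 2, function(ci) max(chi_for(ci)))
  vapply(obs, function(o) mean(maxima >= o - 1e-9), 0)
}

# exhaustive two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
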