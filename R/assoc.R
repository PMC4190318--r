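#' Allelic case-control association test
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' allele counts in cases versus controls. Each diploid individual contributes
#' two alleles; missing genotypes contribute none. Degenerate tables (a zero
#' row or column margin) return chi2 = 0, p = 1. Vectorised over markers.
#'
#' The continuity correction is deliberately omitted: for the complete
#' separation attainable with 5 cases and 12 controls (10 vs 0 minor alleles)
#' the uncorrected statistic equals the total allele count, chi2 = 34, with
#' upper-tail p = 5.5e-9.
#'
#' @param case_alt,case_ref,ctrl_alt,ctrl_ref allele counts (vectors)
#' @return tibble with columns chi2, p_raw
#' @export
allelic_test <- function(case_alt, case_ref, ctrl_alt, ctrl_ref) {
  if (any(c(case_alt, case_ref, ctrl_alt, ctrl_ref) < 0)) {
    stop("allele counts must be non-negative")
  }
  chi2 <- chi2_2x2(case_alt, case_ref, ctrl_alt, ctrl_ref)
  tibble::tibble(chi2 = chi2,
                 p_raw = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# vectorised Pearson chi-square for 2x2 tables; 0 when a margin is empty
chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  out <- n * (a * d - b * c)^2 / denom
  out[denom == 0] <- 0
  as.numeric(out)
}

#' Bonferroni correction
#'
#' @param p_raw raw p-value(s)
#' @param m number of tests (retained markers)
#' @return pmin(1, m * p_raw)
#' @export
bonferroni_p <- function(p_raw, m) {
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p_raw)
}

#' Genomic inflation factor
#'
#' lambda = median(chi2) / qchisq(0.5, df = 1); values well above 1 indicate
#' stratification or cryptic relatedness inflating the test statistics.
#'
#' @param chi2_values per-marker 1-df chi-square statistics
#' @return lambda
#' @export
genomic_inflation <- function(chi2_values) {
  chi2_values <- chi2_values[is.finite(chi2_values)]
  if (length(chi2_values) == 0) stop("no finite statistics")
  stats::median(chi2_values) / stats::qchisq(0.5, df = 1)
}

# per-marker case/control allele counts for a given case indicator,
# excluding missing genotypes
allele_counts <- function(m, is_case) {
  mm <- m; mm[is.na(mm)] <- 0L
  ok <- !is.na(m)
  case_alt <- colSums(mm[is_case, , drop = FALSE])
  ctrl_alt <- colSums(mm[!is_case, , drop = FALSE])
  case_n <- colSums(ok[is_case, , drop = FALSE])
  ctrl_n <- colSums(ok[!is_case, , drop = FALSE])
  tibble::tibble(
    case_alt = case_alt, case_ref = 2L * case_n - case_alt,
    ctrl_alt = ctrl_alt, ctrl_ref = 2L * ctrl_n - ctrl_alt
  )
}

#' Genome-wide allelic association scan
#'
#' Runs [allelic_test()] at every marker, attaches Bonferroni-corrected
#' p-values (m = number of markers scanned) and the genomic inflation factor.
#' Cases are the samples whose phenotype is `affected` in the sample table.
#'
#' @param gt wide genotype tibble (post-QC)
#' @param samples sample table with `sample_id` and `phenotype`
#' @return tibble of class `recmapr_scan`: marker_id, chrom, pos, allele
#'   counts, chi2, p_raw, p_bonf; attributes `lambda`, `m`, `n_cases`,
#'   `n_controls`
#' @export
assoc_scan <- function(gt, samples) {
  validate_marker_map(gt)
  ids <- sample_cols(gt)
  ph <- samples$phenotype[match(ids, samples$sample_id)]
  if (anyNA(ph)) stop("samples in genotype table missing from sample table")
  is_case <- ph == "affected"
  if (sum(is_case) == 0 || sum(!is_case) == 0) {
    stop("need at least one case and one control")
  }
  m <- geno_matrix(gt, ids)
  cnt <- allele_counts(m, is_case)
  tst <- allelic_test(cnt$case_alt, cnt$case_ref, cnt$ctrl_alt, cnt$ctrl_ref)
  out <- dplyr::bind_cols(
    gt[, c("marker_id", "chrom", "pos")], cnt, tst)
  out$p_bonf <- bonferroni_p(out$p_raw, nrow(out))
  structure(out,
            class = c("recmapr_scan", class(tibble::tibble()))
            , lambda = genomic_inflation(out$chi2), m = nrow(out),
            n_cases = sum(is_case), n_controls = sum(!is_case))
}

#' Permutation configuration
#'
#' @param n_perm number of phenotype permutations (default 100,000)
#' @param seed integer seed
#' @return a `perm_config` list
#' @export
perm_config <- function(n_perm = 1e5, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "perm_config")
}

#' Max-T permutation genome-wide empirical p-values
#'
#' Shuffles case/control labels (case count fixed), recomputes the allelic
#' chi-square at every marker, and records the genome-wide maximum of each
#' permutation. The empirical p-value at a marker is (r + 1) / (R + 1), where
#' r counts permutations whose maximum statistic is >= the observed statistic
#' at that marker (ties count as exceedances). Permutations are processed in
#' fixed-size chunks so memory stays flat; results are deterministic given
#' the seed.
#'
#' @param gt wide genotype tibble (post-QC)
#' @param samples sample table with `sample_id` and `phenotype`
#' @param perm a [perm_config()]
#' @param chunk_size permutations per chunk (fixed; part of the deterministic
#'   stream)
#' @return tibble: marker_id, chi2, p_emp
#' @export
maxt_permutation <- function(gt, samples, perm = perm_config(),
                             chunk_size = 2000L) {
  stopifnot(inherits(perm, "perm_config"))
  ids <- sample_cols(gt)
  ph <- samples$phenotype[match(ids, samples$sample_id)]
  if (anyNA(ph)) stop("samples in genotype table missing from sample table")
  is_case <- ph == "affected"
  n_case <- sum(is_case)
  n <- length(ids)
  m <- geno_matrix(gt, ids)
  obs <- allele_counts(m, is_case)
  chi2_obs <- chi2_2x2(obs$case_alt, obs$case_ref, obs$ctrl_alt, obs$ctrl_ref)

  mm <- m; mm[is.na(mm)] <- 0
  ok <- (!is.na(m)) * 1
  tot_alt <- colSums(mm)
  tot_n <- colSums(ok)

  set.seed(perm$seed)
  R <- perm$n_perm
  r <- numeric(length(chi2_obs))
  done <- 0L
  while (done < R) {
    k <- min(chunk_size, R - done)
    # rank random keys per column to draw k label shuffles at once
    keys <- matrix(stats::runif(n * k), n, k)
    ranks <- matrix(0L, n, k)
    for (j in seq_len(k)) ranks[, j] <- order(keys[, j])
    sel <- matrix(0, n, k)
    sel[cbind(as.vector(ranks[seq_len(n_case), ]),
              rep(seq_len(k), each = n_case))] <- 1
    case_alt <- crossprod(mm, sel)            # markers x k
    case_n <- crossprod(ok, sel)
    case_ref <- 2 * case_n - case_alt
    ctrl_alt <- tot_alt - case_alt
    ctrl_ref <- 2 * (tot_n - case_n) - ctrl_alt
    chi2 <- chi2_2x2(case_alt, case_ref, ctrl_alt, ctrl_ref)
    dim(chi2) <- dim(case_alt)
    tc <- t(chi2)
    mx <- tc[cbind(seq_len(k), max.col(tc, ties.method = "first"))]
    mx_sorted <- sort(mx)
    # exceedance count with ties included: maxima >= observed statistic
    r <- r + (k - findInterval(chi2_obs - 1e-9, mx_sorted))
    done <- done + k
  }
  tibble::tibble(marker_id = gt$marker_id, chi2 = chi2_obs,
                 p_emp = (r + 1) / (R + 1))
}
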