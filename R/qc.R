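#' Marker quality-control thresholds
#'
#' @param min_call_rate minimum fraction of samples with a genotype call
#'   (default 0.90)
#' @param min_maf minimum cohort minor-allele frequency (default 0.05)
#' @param min_hwe_p minimum Hardy-Weinberg exact-test p-value over the whole
#'   cohort (default 1e-5)
#' @return a `qc_thresholds` list
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_maf = 0.05,
                          min_hwe_p = 1e-5) {
  th <- list(min_call_rate = min_call_rate, min_maf = min_maf,
             min_hwe_p = min_hwe_p)
  if (any(unlist(th) < 0 | unlist(th) > 1)) stop("thresholds must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Filter array markers on call rate, MAF and Hardy-Weinberg equilibrium
#'
#' Markers are tested in the fixed order call rate, MAF, HWE, and each removed
#' marker is attributed to the first rule it fails. Call rate counts all
#' samples in the denominator; allele frequencies and HWE genotype counts use
#' non-missing calls only, pooled over the whole cohort.
#'
#' @param gt wide genotype tibble
#' @param thresholds a [qc_thresholds()] object
#' @param samples optional character vector of samples to use
#' @return list: `genotypes` (retained markers), `report` (per-reason removal
#'   counts, in order), `removed` (marker_id + reason), `m` (retained count).
#'   Removing every marker is a warning, not an error.
#' @export
qc_filter <- function(gt, thresholds = qc_thresholds(), samples = NULL) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  validate_marker_map(gt)
  if (length(samples %||% sample_cols(gt)) < 1) stop("need at least 1 sample")
  st <- marker_stats(gt, samples)
  m <- geno_matrix(gt, samples)
  hwe <- apply(m, 2, function(g) {
    g <- g[!is.na(g)]
    hwe_exact_p(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  fail_cr <- st$call_rate < thresholds$min_call_rate
  fail_maf <- !fail_cr & (is.na(st$maf) | st$maf < thresholds$min_maf)
  fail_hwe <- !fail_cr & !fail_maf & hwe < thresholds$min_hwe_p
  reason <- dplyr::case_when(
    fail_cr ~ "call_rate", fail_maf ~ "maf", fail_hwe ~ "hwe",
    .default = NA_character_)
  keep <- is.na(reason)
  report <- tibble::tibble(
    reason = c("call_rate", "maf", "hwe"),
    n_removed = c(sum(fail_cr), sum(fail_maf), sum(fail_hwe))
  )
  if (!any(keep)) warning("all markers removed by QC")
  list(
    genotypes = gt[keep, , drop = FALSE],
    report = report,
    removed = tibble::tibble(marker_id = gt$marker_id[!keep],
                             reason = reason[!keep]),
    m = sum(keep)
  )
}

#' Exact test of Hardy-Weinberg equilibrium from genotype counts
#'
#' Two-sided exact test using the probability-ordering convention: the p-value
#' sums, over all heterozygote counts compatible with the observed allele
#' counts, the conditional probabilities no larger than that of the observed
#' configuration. Monomorphic markers return 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative, total >= 1)
#' @return p-value in (0, 1]
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("need at least one genotyped individual")
  n1 <- 2L * min(n_hom_ref, n_hom_alt) + n_het   # rarer allele count
  if (n1 == 0L) return(1)
  hs <- seq(n1 %% 2L, min(n1, 2L * n - n1), by = 2L)
  # P(h | n, n1) on the log scale; constant terms cancel in normalisation
  logp <- h_logprob(hs, n, n1)
  p_obs <- logp[hs == n_het]
  probs <- exp(logp - max(logp))
  sum(probs[logp <= p_obs + 1e-10]) / sum(probs)
}

h_logprob <- function(h, n, n1) {
  n_aa <- (n1 - h) / 2
  n_bb <- n - h - n_aa
  h * log(2) - lgamma(h + 1) - lgamma(n_aa + 1) - lgamma(n_bb + 1)
}
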