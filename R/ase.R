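#' Allele-balance test for allele-specific expression
#'
#' A heterozygote's two alleles should appear in cDNA in the same proportion
#' as in genomic DNA unless the transcript of one allele is lost (for
#' example by nonsense-mediated decay). This test compares the 2x2 table of
#' (gDNA vs cDNA) x (ref vs alt) counts with a two-sided Fisher exact test
#' and guards the verdict with an effect-size threshold: the observation is
#' `balanced` iff p > alpha and the fold change is below `fc_threshold`. The
#' fold change is the largest ratio (cDNA vs gDNA, either direction) of
#' either allele's fraction, which makes it symmetric under relabelling the
#' two alleles; add-half continuity is applied when any cell is zero.
#'
#' @param obs tibble with columns gdna_ref, gdna_alt, cdna_ref, cdna_alt
#'   (non-negative; each template's total must be >= 1). Vectorised over rows.
#' @param alpha significance level (default 0.05)
#' @param fc_threshold fold-change guard (default 1.5)
#' @return tibble of class `ase_result`: input counts plus gdna_ratio,
#'   cdna_ratio, fold_change, p, verdict
#' @export
allele_balance_test <- function(obs, alpha = 0.05, fc_threshold = 1.5) {
  need <- c("gdna_ref", "gdna_alt", "cdna_ref", "cdna_alt")
  stopifnot(all(need %in% names(obs)))
  cnt <- as.matrix(obs[, need])
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (any(rowSums(cnt[, 1:2, drop = FALSE]) < 1) ||
      any(rowSums(cnt[, 3:4, drop = FALSE]) < 1)) {
    stop("each of gDNA and cDNA needs at least one observed allele")
  }
  res <- purrr::map_dfr(seq_len(nrow(cnt)), function(i) {
    x <- cnt[i, ]
    tab <- matrix(x, nrow = 2, byrow = TRUE)   # rows gdna/cdna, cols ref/alt
    p <- stats::fisher.test(tab)$p.value
    g_ratio <- x["gdna_alt"] / (x["gdna_ref"] + x["gdna_alt"])
    c_ratio <- x["cdna_alt"] / (x["cdna_ref"] + x["cdna_alt"])
    xc <- if (any(x == 0)) x + 0.5 else x
    f1 <- xc["gdna_alt"] / (xc["gdna_ref"] + xc["gdna_alt"])
    f2 <- xc["cdna_alt"] / (xc["cdna_ref"] + xc["cdna_alt"])
    fc <- max(f1 / f2, f2 / f1, (1 - f1) / (1 - f2), (1 - f2) / (1 - f1))
    tibble::tibble(gdna_ratio = unname(g_ratio), cdna_ratio = unname(c_ratio),
                   fold_change = unname(fc), p = p,
                   verdict = if (p > alpha && fc < fc_threshold) "balanced"
                             else "imbalanced")
  })
  out <- dplyr::bind_cols(tibble::as_tibble(obs), res)
  structure(out, class = c("ase_result", class(tibble::tibble())),
            alpha = alpha, fc_threshold = fc_threshold)
}

#' Read / write allele-count tables for ASE testing
#'
#' Four count columns, tab separated, one row per assayed site.
#'
#' @param path file path
#' @return tibble with gdna_ref, gdna_alt, cdna_ref, cdna_alt (+ any id cols)
#' @export
read_ase_counts <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gdna_ref", "gdna_alt", "cdna_ref", "cdna_alt")
  if (!all(need %in% names(tab))) {
    stop("ASE counts need columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' @rdname read_ase_counts
#' @param counts tibble of counts
#' @export
write_ase_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}
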