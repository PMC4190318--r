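#' Genotype tables
#'
#' Throughout recmapr, array genotypes and sequence variants travel as a single
#' wide tibble: one row per marker (or variant), marker metadata in leading
#' columns, and one integer genotype column per sample. Genotype codes are
#' `0` = homozygous reference/major, `1` = heterozygous, `2` = homozygous
#' alternate/minor, `NA` = missing. Every downstream module consumes only this
#' encoding.
#'
#' Array genotype tables carry the metadata columns `marker_id`, `chrom`,
#' `pos`, `a1`, `a2` (a2 is the minor allele over the loaded cohort, so that
#' code 2 counts minor alleles). Variant tables from [read_vcf()] carry
#' `variant_id`, `chrom`, `pos`, `ref`, `alt`.
#'
#' @param gt a genotype tibble
#' @name geno-table
NULL

.geno_meta_cols <- c("marker_id", "chrom", "pos", "a1", "a2")
.variant_meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt")

#' @describeIn geno-table sample-id columns of a genotype or variant tibble
#' @export
sample_cols <- function(gt) {
  setdiff(names(gt), c(.geno_meta_cols, .variant_meta_cols))
}

#' @describeIn geno-table extract the samples x markers integer call matrix
#'   (samples in columns of the tibble become rows of the matrix)
#' @param samples optional character vector restricting/ordering samples
#' @export
geno_matrix <- function(gt, samples = NULL) {
  samples <- samples %||% sample_cols(gt)
  missing <- setdiff(samples, names(gt))
  if (length(missing) > 0) {
    stop("samples absent from genotype table: ", paste(missing, collapse = ", "))
  }
  m <- t(as.matrix(as.data.frame(gt)[, samples, drop = FALSE]))
  storage.mode(m) <- "integer"
  rownames(m) <- samples
  colnames(m) <- if ("marker_id" %in% names(gt)) gt$marker_id else gt$variant_id
  m
}

#' Assemble a genotype tibble from a call matrix and a marker map
#'
#' @param calls integer matrix, samples in rows, markers in columns; values in
#'   {0, 1, 2, NA}
#' @param map tibble with columns marker_id, chrom, pos, a1, a2
#' @return wide genotype tibble (see [geno-table])
#' @export
as_geno_table <- function(calls, map) {
  stopifnot(is.matrix(calls), nrow(map) == ncol(calls))
  validate_marker_map(map)
  bad <- calls[!is.na(calls)]
  if (length(bad) > 0 && (min(bad) < 0 || max(bad) > 2)) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  gt <- dplyr::bind_cols(
    tibble::as_tibble(map[, .geno_meta_cols]),
    tibble::as_tibble(t(calls), .name_repair = "minimal")
  )
  names(gt)[-seq_along(.geno_meta_cols)] <- rownames(calls)
  gt
}

validate_marker_map <- function(map) {
  req <- c("marker_id", "chrom", "pos")
  if (!all(req %in% names(map))) {
    stop("marker map needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(map$marker_id)) stop("duplicated marker_id in map")
  ooo <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(sorted = !is.unsorted(.data$pos, strictly = TRUE))
  if (!all(ooo$sorted)) {
    stop("marker positions must be strictly increasing within chromosome")
  }
  invisible(map)
}

#' Per-marker call rate and minor allele frequency
#'
#' Call rate uses all samples in the denominator; allele frequencies are
#' computed over non-missing calls only.
#'
#' @inheritParams geno-table
#' @param samples samples to use (default: all genotype columns)
#' @return tibble with marker_id, n_called, call_rate, maf
#' @export
marker_stats <- function(gt, samples = NULL) {
  m <- geno_matrix(gt, samples)
  n <- nrow(m)
  called <- colSums(!is.na(m))
  alt <- colSums(m, na.rm = TRUE)
  af <- ifelse(called > 0, alt / (2 * called), NA_real_)
  tibble::tibble(
    marker_id = colnames(m),
    n_called = as.integer(called),
    call_rate = called / n,
    maf = pmin(af, 1 - af)
  )
}

#' Re-orient genotype codes so that code 2 counts the minor allele
#'
#' Array platforms code alleles arbitrarily; association statistics must not
#' depend on that choice. At load time we flip markers whose coded alternate
#' allele is the major allele in the cohort (swapping a1/a2 and mapping
#' 0 <-> 2), and record the flip in the `flipped` attribute.
#'
#' @inheritParams geno-table
#' @return genotype tibble with a2 the cohort minor allele at every marker
#' @export
orient_to_minor <- function(gt) {
  m <- geno_matrix(gt)
  called <- colSums(!is.na(m))
  af <- ifelse(called > 0, colSums(m, na.rm = TRUE) / (2 * called), 0)
  flip <- af > 0.5
  if (any(flip)) {
    m[, flip] <- 2L - m[, flip]
    a1 <- gt$a1
    gt$a1[flip] <- gt$a2[flip]
    gt$a2[flip] <- a1[flip]
    gt[, sample_cols(gt)] <- tibble::as_tibble(t(m), .name_repair = "minimal")
  }
  attr(gt, "flipped") <- gt$marker_id[flip]
  gt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
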