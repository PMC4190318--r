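#' Read biallelic SNVs from a VCF file
#'
#' Consumes VCF 4.x through vcfR and returns a wide variant tibble (columns
#' `variant_id`, `chrom`, `pos`, `ref`, `alt`, then one integer genotype
#' column per sample). Only biallelic single-nucleotide rows are kept;
#' multi-allelic rows, indels and symbolic alleles are skipped and their count
#' reported via the `n_skipped` attribute and a message. Phased and unphased
#' genotypes are treated identically.
#'
#' @param path VCF file (plain text or bgzip)
#' @param sample_filter optional character vector of samples to keep
#' @return variant tibble; attribute `n_skipped` carries the skip count
#' @export
read_vcf <- function(path, sample_filter = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  if (nrow(fix) == 0) {
    out <- tibble::tibble(variant_id = character(), chrom = character(),
                          pos = integer(), ref = character(), alt = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2) stop("VCF has no genotype columns")
  fmt <- gt_raw[, "FORMAT"]
  if (any(!grepl("(^|:)GT(:|$)", fmt))) stop("missing GT in FORMAT field")

  snv <- !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snv)
  if (n_skip > 0) {
    message(sprintf("read_vcf: skipped %d non-SNV/multi-allelic row(s)", n_skip))
  }

  samples <- colnames(gt_raw)[-1]
  if (!is.null(sample_filter)) {
    unknown <- setdiff(sample_filter, samples)
    if (length(unknown) > 0) {
      stop("sample(s) not in VCF: ", paste(unknown, collapse = ", "))
    }
    samples <- sample_filter
  }

  gt_field <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- sub(":.*$", "", x)
    x <- gsub("\\|", "/", x)
    dplyr::case_match(x, "0/0" ~ 0L, "0/1" ~ 1L, "1/0" ~ 1L, "1/1" ~ 2L,
                      .default = NA_integer_)
  }
  calls <- matrix(NA_integer_, sum(snv), length(samples))
  for (k in seq_along(samples)) {
    calls[, k] <- code(gt_field[snv, samples[k]])
  }

  fix <- fix[snv, , drop = FALSE]
  out <- tibble::tibble(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  out[samples] <- tibble::as_tibble(calls, .name_repair = "minimal")
  attr(out, "n_skipped") <- n_skip
  out
}

#' Write a variant tibble as plain-text VCF 4.2
#'
#' Emits a GT-only FORMAT. Input must already be sorted by (chrom, pos);
#' unsorted input is an error rather than being silently reordered.
#'
#' @param variants variant tibble as produced by [read_vcf()]
#' @param samples character vector of sample columns to write, in order
#' @param path output path
#' @return invisibly, `path`
#' @export
write_vcf <- function(variants, samples, path) {
  # chromosomes must form contiguous blocks with ascending positions inside
  blocks <- rle(variants$chrom)$values
  if (anyDuplicated(blocks) ||
      any(tapply(variants$pos, factor(variants$chrom, levels = blocks),
                 is.unsorted))) {
    stop("variants must be sorted by (chrom, pos) before writing")
  }
  if (any(variants$ref == variants$alt)) stop("ref allele equals alt allele")
  missing <- setdiff(samples, names(variants))
  if (length(missing) > 0) {
    stop("sample(s) not in variant table: ", paste(missing, collapse = ", "))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=recmapr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_str <- function(g) {
    dplyr::case_match(g, 0L ~ "0/0", 1L ~ "0/1", 2L ~ "1/1",
                      .default = "./.")
  }
  body <- character(nrow(variants))
  if (nrow(variants) > 0) {
    gmat <- vapply(samples, function(s) gt_str(variants[[s]]),
                   character(nrow(variants)))
    if (is.null(dim(gmat))) gmat <- matrix(gmat, nrow = nrow(variants))
    body <- paste(variants$chrom, variants$pos, variants$variant_id,
                  variants$ref, variants$alt, ".", ".", ".", "GT",
                  apply(gmat, 1, paste, collapse = "\t"),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
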