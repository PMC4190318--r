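#' Transcript model for coordinate arithmetic
#'
#' A minimal exon-table transcript: ordered, non-overlapping exons in genomic
#' coordinates (1-based inclusive), a strand, and the offset of the first
#' coding base within the spliced transcript (0 when c.1 is the first spliced
#' base).
#'
#' @param exons tibble/data frame with columns start, end (1-based inclusive,
#'   sorted by genomic position, non-overlapping)
#' @param strand "+" or "-"
#' @param cds_offset bases of the spliced transcript preceding the start
#'   codon (default 0)
#' @param gene_id optional label
#' @return a `transcript_model`
#' @export
transcript_model <- function(exons, strand, cds_offset = 0, gene_id = "gene") {
  stopifnot(strand %in% c("+", "-"), all(exons$end >= exons$start))
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(utils::head(exons$end, -1) >= utils::tail(exons$start, -1))) {
    stop("exons must be sorted and non-overlapping")
  }
  spliced <- sum(exons$end - exons$start + 1)
  if (spliced - cds_offset < 3) stop("spliced coding length must be >= 3")
  structure(list(exons = tibble::as_tibble(exons[, c("start", "end")]),
                 strand = strand, cds_offset = cds_offset,
                 gene_id = gene_id, spliced_length = spliced),
            class = "transcript_model")
}

#' Convert a coding-DNA position to protein residue and codon offset
#'
#' c.1 is the first base of the start codon; residue index is the ceiling of
#' cdna_pos / 3 and codon_offset in 1..3 satisfies
#' 3 * (residue - 1) + offset = cdna_pos.
#'
#' @param cdna_pos coding position(s), >= 1
#' @return tibble: cdna_pos, residue_index, codon_offset
#' @export
cdna_to_protein <- function(cdna_pos) {
  if (any(cdna_pos < 1)) stop("cdna_pos must be >= 1")
  residue <- ceiling(cdna_pos / 3)
  tibble::tibble(cdna_pos = cdna_pos,
                 residue_index = as.integer(residue),
                 codon_offset = as.integer(cdna_pos - 3 * (residue - 1)))
}

#' Map genomic positions onto a transcript's coding coordinates
#'
#' Exonic positions return the coding coordinate (on the minus strand,
#' numbering decreases with genomic position); intronic positions return the
#' nearest-exon offset in HGVS style (`c.N+k` downstream of a coding base,
#' `c.N-k` upstream of the next one).
#'
#' @param position_bp genomic position(s) within the transcript span
#' @param tm a [transcript_model()]
#' @return tibble: position_bp, region ("exonic"/"intronic"), cdna_pos (NA
#'   when intronic), label (HGVS-style c. string)
#' @export
genomic_to_cdna <- function(position_bp, tm) {
  stopifnot(inherits(tm, "transcript_model"))
  ex <- tm$exons
  span <- c(ex$start[1], ex$end[nrow(ex)])
  if (any(position_bp < span[1] | position_bp > span[2])) {
    stop("position outside transcript span")
  }
  len <- ex$end - ex$start + 1
  cum_before <- cumsum(c(0, utils::head(len, -1)))
  out <- lapply(position_bp, function(p) {
    k <- which(p >= ex$start & p <= ex$end)
    if (length(k) == 1) {
      spliced_plus <- cum_before[k] + (p - ex$start[k]) + 1
      spliced <- if (tm$strand == "+") spliced_plus
                 else tm$spliced_length - spliced_plus + 1
      cdna <- spliced - tm$cds_offset
      tibble::tibble(position_bp = p, region = "exonic",
                     cdna_pos = as.integer(cdna),
                     label = paste0("c.", cdna))
    } else {
      up <- max(which(ex$end < p))      # exon genomically left of p
      d_left <- p - ex$end[up]
      d_right <- ex$start[up + 1] - p
      left_c <- genomic_to_cdna(ex$end[up], tm)$cdna_pos
      right_c <- genomic_to_cdna(ex$start[up + 1], tm)$cdna_pos
      # on the plus strand the left exon end is the last coding base before
      # the intron; on the minus strand it is the first one after it
      if (tm$strand == "+") {
        lab <- if (d_left <= d_right) paste0("c.", left_c, "+", d_left)
               else paste0("c.", right_c, "-", d_right)
      } else {
        lab <- if (d_right <= d_left) paste0("c.", right_c, "+", d_right)
               else paste0("c.", left_c, "-", d_left)
      }
      tibble::tibble(position_bp = p, region = "intronic",
                     cdna_pos = NA_integer_, label = lab)
    }
  })
  dplyr::bind_rows(out)
}

#' Recover a genomic position from a coding coordinate
#'
#' Inverse of [genomic_to_cdna()] for exonic positions.
#'
#' @param cdna_pos coding position(s)
#' @param tm a [transcript_model()]
#' @return genomic position(s)
#' @export
cdna_to_genomic <- function(cdna_pos, tm) {
  stopifnot(inherits(tm, "transcript_model"))
  spliced <- cdna_pos + tm$cds_offset
  if (any(spliced < 1 | spliced > tm$spliced_length)) {
    stop("cdna position outside transcript")
  }
  ex <- tm$exons
  len <- ex$end - ex$start + 1
  cum <- cumsum(len)
  vapply(spliced, function(s) {
    sp <- if (tm$strand == "+") s else tm$spliced_length - s + 1
    k <- which(sp <= cum)[1]
    before <- if (k == 1) 0 else cum[k - 1]
    ex$start[k] + (sp - before) - 1
  }, 0)
}

#' Infer transcript strand from paired genomic/cDNA coordinates
#'
#' @param pairs tibble with columns genomic_pos and cdna_pos (>= 2 rows)
#' @return "+" when cDNA numbering increases with genomic position, "-" when
#'   it strictly decreases; inconsistent (non-monotone) pairs are an error
#' @export
infer_strand <- function(pairs) {
  if (nrow(pairs) < 2) stop("need at least 2 coordinate pairs")
  ord <- order(pairs$genomic_pos)
  d <- diff(pairs$cdna_pos[ord])
  if (all(d > 0)) return("+")
  if (all(d < 0)) return("-")
  stop("inconsistent coordinate pairs: cDNA numbering is not monotone")
}

#' Classify the coding effect of a codon substitution
#'
#' Translates both codons with the standard genetic code: identical amino
#' acids are synonymous, a gained stop is nonsense, anything else missense.
#'
#' @param ref_codon,alt_codon 3-base codons (A/C/G/T)
#' @return tibble: ref_codon, alt_codon, ref_aa, alt_aa, effect
#' @export
classify_effect <- function(ref_codon, alt_codon) {
  tr <- function(x) {
    x <- toupper(x)
    if (any(!grepl("^[ACGT]{3}$", x))) stop("invalid codon")
    unname(Biostrings::GENETIC_CODE[x])
  }
  ref_aa <- tr(ref_codon)
  alt_aa <- tr(alt_codon)
  effect <- dplyr::case_when(
    ref_aa == alt_aa ~ "synonymous",
    alt_aa == "*" ~ "nonsense",
    .default = "missense"
  )
  tibble::tibble(ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa, effect = effect)
}

#' Count annotated records by effect class
#'
#' Records flagged as probable reference-assembly errors are reported in
#' their own class, separate from the translated effects.
#'
#' @param records tibble with an `effect` column; rows whose effect is
#'   `assembly_error_flag` (or with `assembly_error == TRUE`) are counted
#'   apart
#' @return tibble: effect, n
#' @export
count_by_effect <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(effect = character(), n = integer()))
  }
  eff <- records$effect
  if ("assembly_error" %in% names(records)) {
    eff[records$assembly_error] <- "assembly_error_flag"
  }
  dplyr::count(tibble::tibble(effect = eff), .data$effect, name = "n")
}

#' Parse HGVS-style c. and p. substitution strings
#'
#' Handles simple substitutions only ("c.6845T>A", "p.I2282N"); anything else
#' yields NA fields.
#'
#' @param x character vector of c. strings
#' @return tibble: cdna_pos, cdna_ref, cdna_alt
#' @export
parse_hgvs_c <- function(x) {
  m <- regmatches(x, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", x))
  tibble::tibble(
    cdna_pos = vapply(m, function(g) if (length(g) == 4) as.integer(g[2]) else NA_integer_, 0L),
    cdna_ref = vapply(m, function(g) if (length(g) == 4) g[3] else NA_character_, ""),
    cdna_alt = vapply(m, function(g) if (length(g) == 4) g[4] else NA_character_, "")
  )
}

#' @rdname parse_hgvs_c
#' @param p character vector of p. strings
#' @return for [parse_hgvs_p()]: tibble ref_aa, residue_index, alt_aa
#' @export
parse_hgvs_p <- function(p) {
  m <- regmatches(p, regexec("^p\\.([A-Z])([0-9]+)([A-Z])$", p))
  tibble::tibble(
    ref_aa = vapply(m, function(g) if (length(g) == 4) g[2] else NA_character_, ""),
    residue_index = vapply(m, function(g) if (length(g) == 4) as.integer(g[3]) else NA_integer_, 0L),
    alt_aa = vapply(m, function(g) if (length(g) == 4) g[4] else NA_character_, "")
  )
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of A/C/G/T strings
#' @return reverse-complemented strings
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
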