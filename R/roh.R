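#' Run-of-homozygosity parameters
#'
#' Defaults mirror the classical settings for sparse-array autozygosity
#' mapping: runs of at least 25 informative SNPs spanning at least 500 kb,
#' tolerating at most one heterozygous call inside a run; shared segments
#' require identical homozygous alleles in at least 95% of pairwise case
#' comparisons per marker.
#'
#' @param min_length_kb minimum run length in kb (default 500)
#' @param min_snps minimum non-missing markers in a run (default 25)
#' @param max_het heterozygous calls tolerated inside a run (default 1)
#' @param match_frac minimum fraction of identical pairwise comparisons for a
#'   marker to count as shared (default 0.95)
#' @return a `roh_params` list
#' @export
roh_params <- function(min_length_kb = 500, min_snps = 25, max_het = 1,
                       match_frac = 0.95) {
  if (min_snps < 1) stop("min_snps must be >= 1")
  if (match_frac <= 0 || match_frac > 1) stop("match_frac must be in (0, 1]")
  structure(list(min_length_kb = min_length_kb, min_snps = as.integer(min_snps),
                 max_het = as.integer(max_het), match_frac = match_frac),
            class = "roh_params")
}

#' Detect runs of homozygosity in one sample
#'
#' Scans each chromosome for maximal runs of non-missing homozygous calls
#' permitting at most `max_het` heterozygous calls per run. Missing calls do
#' not break a run but count toward neither the SNP total nor the
#' heterozygote total; `n_snps` counts the homozygous informative calls and
#' tolerated heterozygotes are tallied separately in `n_het_inside`. Runs are
#' trimmed to homozygous end markers, and runs with fewer than `min_snps`
#' homozygous calls or spanning less than `min_length_kb` kb are discarded.
#'
#' @param gt wide genotype tibble (positions sorted within chromosome)
#' @param sample_id the sample to scan
#' @param params a [roh_params()]
#' @return tibble: sample_id, chrom, first_marker, last_marker, start_bp,
#'   end_bp, n_snps, n_het_inside
#' @export
detect_roh <- function(gt, sample_id, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  validate_marker_map(gt)
  if (!sample_id %in% names(gt)) stop("unknown sample: ", sample_id)
  g_all <- gt[[sample_id]]
  out <- lapply(split(seq_len(nrow(gt)), gt$chrom), function(rows) {
    .roh_one_chrom(g_all[rows], gt$pos[rows], gt$marker_id[rows],
                   gt$chrom[rows][1], sample_id, params)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0) res <- dplyr::arrange(res, .data$chrom, .data$start_bp)
  res
}

.roh_one_chrom <- function(g, pos, ids, chrom, sample_id, params) {
  empty <- tibble::tibble(sample_id = character(), chrom = character(),
                          first_marker = character(), last_marker = character(),
                          start_bp = integer(), end_bp = integer(),
                          n_snps = integer(), n_het_inside = integer())
  idx <- which(!is.na(g))
  if (length(idx) == 0) return(empty)
  s <- g[idx]                       # 0/1/2 over non-missing markers
  n <- length(s)
  het <- which(s == 1L)
  k <- params$max_het
  # maximal windows with <= k heterozygotes, delimited by the (k+1)-th
  # heterozygote on either side
  bnd <- c(0L, het, n + 1L)
  # with <= max_het heterozygotes in total the whole sequence is one window
  n_win <- max(length(bnd) - k - 1L, 1L)
  segs <- list()
  for (w in seq_len(n_win)) {
    lo <- bnd[w] + 1L
    hi <- bnd[min(w + k + 1L, length(bnd))] - 1L
    if (hi < lo) next
    # trim to homozygous end markers
    rng <- lo:hi
    hom <- rng[s[rng] != 1L]
    if (length(hom) == 0) next
    a <- hom[1]; b <- hom[length(hom)]
    segs[[length(segs) + 1L]] <- c(a, b)
  }
  if (length(segs) == 0) return(empty)
  sm <- unique(do.call(rbind, segs))
  # drop windows nested inside another after trimming
  if (nrow(sm) > 1) {
    o <- order(sm[, 1], -sm[, 2])
    sm <- sm[o, , drop = FALSE]
    keep <- sm[, 2] > cummax(c(-1L, utils::head(sm[, 2], -1)))
    sm <- sm[keep, , drop = FALSE]
  }
  a <- sm[, 1]; b <- sm[, 2]
  cum_het <- cumsum(s == 1L)
  n_het_in <- cum_het[b] - cum_het[a] + (s[a] == 1L)
  n_snps <- (b - a + 1L) - n_het_in    # homozygous informative calls
  i1 <- idx[a]; i2 <- idx[b]
  len <- pos[i2] - pos[i1]
  ok <- n_snps >= params$min_snps & len >= params$min_length_kb * 1000
  if (!any(ok)) return(empty)
  tibble::tibble(sample_id = sample_id, chrom = chrom,
                 first_marker = ids[i1[ok]], last_marker = ids[i2[ok]],
                 start_bp = pos[i1[ok]], end_bp = pos[i2[ok]],
                 n_snps = n_snps[ok], n_het_inside = n_het_in[ok])
}

#' Shared autozygous segment across all cases
#'
#' Intersects the cases' runs of homozygosity, then requires, marker by
#' marker, an identical homozygous allele in at least `match_frac` of the
#' pairwise case comparisons. A marker at which any case is heterozygous, or
#' at which cases are homozygous for opposite alleles beyond the match
#' tolerance, breaks the shared run. A missing genotype in a case is
#' compatible (does not break sharing) but the marker only counts toward
#' `n_shared_snps` when every case is genotyped and matching. The longest
#' qualifying segment genome-wide is returned, with bounds extended outward
#' to the nearest flanking marker at which any case is heterozygous or
#' allele-discordant (the printed coordinates of a critical interval are
#' exactly these flanking positions).
#'
#' @param gt wide genotype tibble
#' @param case_ids character vector of >= 2 case samples
#' @param params a [roh_params()]
#' @return one-row tibble (chrom, left_bound_bp, right_bound_bp,
#'   n_shared_snps, first_marker, last_marker, length_bp, length_kb), or a
#'   zero-row tibble when no segment qualifies
#' @export
shared_autozygous_segment <- function(gt, case_ids, params = roh_params()) {
  if (length(case_ids) < 2) stop("need at least 2 cases")
  validate_marker_map(gt)
  m <- geno_matrix(gt, case_ids)          # cases x markers
  n_mark <- ncol(m)

  # markers covered by a qualifying ROH in every case
  covered <- matrix(FALSE, length(case_ids), n_mark)
  for (i in seq_along(case_ids)) {
    roh <- detect_roh(gt, case_ids[i], params)
    for (r in seq_len(nrow(roh))) {
      j <- which(gt$chrom == roh$chrom[r] &
                 gt$pos >= roh$start_bp[r] & gt$pos <= roh$end_bp[r])
      covered[i, j] <- TRUE
    }
  }
  eligible <- colSums(covered) == length(case_ids)

  st <- .share_status(m, params$match_frac)
  status <- st$status
  status[status != "break" & !eligible] <- "break"

  runs <- .share_runs(status, gt$chrom)
  if (nrow(runs) == 0) return(.empty_interval())
  runs$n_shared <- vapply(seq_len(nrow(runs)), function(i) {
    sum(status[runs$from[i]:runs$to[i]] == "share")
  }, 0L)
  # anchor bounds at the outermost fully-shared markers
  runs$a <- vapply(seq_len(nrow(runs)), function(i) {
    w <- which(status[runs$from[i]:runs$to[i]] == "share")
    if (length(w) == 0) NA_integer_ else runs$from[i] + w[1] - 1L
  }, 0L)
  runs$b <- vapply(seq_len(nrow(runs)), function(i) {
    w <- which(status[runs$from[i]:runs$to[i]] == "share")
    if (length(w) == 0) NA_integer_ else runs$from[i] + w[length(w)] - 1L
  }, 0L)
  runs <- runs[!is.na(runs$a), , drop = FALSE]
  if (nrow(runs) == 0) return(.empty_interval())
  runs$len <- gt$pos[runs$b] - gt$pos[runs$a]
  # length/SNP thresholds act on the per-case runs (already enforced through
  # ROH eligibility); the intersection only needs >= 2 anchoring markers
  runs <- runs[runs$n_shared >= 2L, , drop = FALSE]
  if (nrow(runs) == 0) return(.empty_interval())
  best <- runs[which.max(runs$len), ]

  chrom_idx <- which(gt$chrom == gt$chrom[best$a])
  gt_break <- st$genotype_break      # het/discordant, ignoring coverage
  left_cand <- chrom_idx[chrom_idx < best$a & gt_break[chrom_idx]]
  right_cand <- chrom_idx[chrom_idx > best$b & gt_break[chrom_idx]]
  left_bp <- if (length(left_cand) > 0) gt$pos[max(left_cand)]
             else gt$pos[chrom_idx[1]]
  right_bp <- if (length(right_cand) > 0) gt$pos[min(right_cand)]
              else gt$pos[chrom_idx[length(chrom_idx)]]

  tibble::tibble(
    chrom = gt$chrom[best$a],
    left_bound_bp = left_bp, right_bound_bp = right_bp,
    n_shared_snps = best$n_shared,
    first_marker = gt$marker_id[best$a], last_marker = gt$marker_id[best$b],
    length_bp = right_bp - left_bp,
    length_kb = round_half_up(right_bp - left_bp, 1000)
  )
}

.empty_interval <- function() {
  tibble::tibble(chrom = character(), left_bound_bp = integer(),
                 right_bound_bp = integer(), n_shared_snps = integer(),
                 first_marker = character(), last_marker = character(),
                 length_bp = integer(), length_kb = integer())
}

# per-marker sharing status across cases:
#   share   -- every case genotyped, homozygous, and pairwise-identical in
#              >= match_frac of comparisons
#   neutral -- some case missing, remaining cases homozygous and matching
#   break   -- any heterozygote, or pairwise identity below match_frac
.share_status <- function(m, match_frac) {
  n_case <- nrow(m)
  status <- character(ncol(m))
  genotype_break <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    g <- m[, j]
    obs <- g[!is.na(g)]
    if (length(obs) == 0) { status[j] <- "neutral"; next }
    if (any(obs == 1L)) {
      status[j] <- "break"; genotype_break[j] <- TRUE; next
    }
    n0 <- sum(obs == 0L); n2 <- sum(obs == 2L)
    pairs <- choose(length(obs), 2)
    ident <- choose(n0, 2) + choose(n2, 2)
    match_ok <- pairs == 0 || (ident / pairs) >= match_frac
    if (!match_ok) {
      status[j] <- "break"; genotype_break[j] <- TRUE
    } else if (length(obs) < n_case) {
      status[j] <- "neutral"
    } else {
      status[j] <- "share"
    }
  }
  list(status = status, genotype_break = genotype_break)
}

# maximal runs of non-break markers, confined to one chromosome
.share_runs <- function(status, chrom) {
  ok <- status != "break"
  grp <- cumsum(!ok | c(TRUE, chrom[-1] != chrom[-length(chrom)]))
  idx <- which(ok)
  if (length(idx) == 0) {
    return(tibble::tibble(from = integer(), to = integer()))
  }
  sp <- split(idx, grp[idx])
  tibble::tibble(
    from = vapply(sp, min, 0L),
    to = vapply(sp, max, 0L)
  )
}

#' Critical-interval length
#'
#' @param left_bound_bp,right_bound_bp flanking marker positions (same
#'   chromosome, left < right)
#' @return tibble: length_bp (difference of bounds) and length_kb (rounded
#'   half-up)
#' @export
interval_length <- function(left_bound_bp, right_bound_bp) {
  if (any(right_bound_bp <= left_bound_bp)) {
    stop("right bound must exceed left bound")
  }
  bp <- right_bound_bp - left_bound_bp
  tibble::tibble(length_bp = bp, length_kb = round_half_up(bp, 1000))
}

round_half_up <- function(x, unit = 1) floor(x / unit + 0.5)

#' Write ROH segments or a critical interval as BED
#'
#' BED is 0-based half-open; the conversion from the package's 1-based
#' inclusive coordinates happens only at this boundary (start - 1, end).
#'
#' @param segments tibble with chrom plus start_bp/end_bp (or
#'   left_bound_bp/right_bound_bp) columns
#' @param path output path
#' @return invisibly, `path`
#' @export
write_bed <- function(segments, path) {
  start <- segments[["start_bp"]] %||% segments[["left_bound_bp"]]
  end <- segments[["end_bp"]] %||% segments[["right_bound_bp"]]
  name <- segments[["sample_id"]] %||% rep("interval", nrow(segments))
  writeLines(sprintf("%s\t%d\t%d\t%s", segments$chrom, start - 1L, end, name),
             path)
  invisible(path)
}
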