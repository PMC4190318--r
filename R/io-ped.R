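#' Read a plink-text PED/MAP pair
#'
#' Reads array genotypes in the classical plink text dialect: a MAP file with
#' one marker per line (chromosome, marker id, genetic distance, bp position)
#' and a PED file with six leading pedigree columns followed by two allele
#' symbols per marker. Allele symbols must be A/C/G/T or `0` for missing; a
#' genotype is missing iff both alleles are `0`. After loading, genotype codes
#' are oriented so that code 2 counts the cohort minor allele
#' (see [orient_to_minor()]).
#'
#' @param ped_path path to the PED file
#' @param map_path path to the MAP file
#' @return list with `genotypes` (wide genotype tibble) and `samples`
#'   (tibble: sample_id, phenotype decoded from the PED phenotype column,
#'   breed = NA, role = NA)
#' @export
read_ped_map <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nt <- lengths(map_tok)
  if (any(nt < 4)) {
    stop(sprintf("map parse error at line %d: expected 4 fields, got %d",
                 which(nt < 4)[1], nt[which(nt < 4)[1]]))
  }
  map <- tibble::tibble(
    chrom = vapply(map_tok, `[`, "", 1),
    marker_id = vapply(map_tok, `[`, "", 2),
    pos = as.integer(vapply(map_tok, `[`, "", 4))
  )
  if (anyNA(map$pos)) {
    stop(sprintf("map parse error at line %d: non-integer position",
                 which(is.na(map$pos))[1]))
  }
  n_mark <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_samp <- length(ped_lines)
  if (n_samp == 0) stop("empty PED file")
  a1 <- matrix(NA_character_, n_samp, n_mark)
  a2 <- matrix(NA_character_, n_samp, n_mark)
  sample_id <- character(n_samp)
  pheno_code <- character(n_samp)
  ok_sym <- c("A", "C", "G", "T", "0")
  for (i in seq_len(n_samp)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * n_mark) {
      stop(sprintf(
        "ped structural error at line %d: expected %d fields for %d markers, got %d",
        i, 6 + 2 * n_mark, n_mark, length(tok)))
    }
    al <- tok[-(1:6)]
    if (!all(al %in% ok_sym)) {
      stop(sprintf("ped parse error at line %d: invalid allele symbol '%s'",
                   i, setdiff(al, ok_sym)[1]))
    }
    sample_id[i] <- tok[2]
    pheno_code[i] <- tok[6]
    a1[i, ] <- al[c(TRUE, FALSE)]
    a2[i, ] <- al[c(FALSE, TRUE)]
  }
  if (anyDuplicated(sample_id)) stop("duplicated sample ids in PED")

  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    stop(sprintf("ped parse error at line %d: half-missing genotype",
                 which(rowSums(half) > 0)[1]))
  }
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA

  calls <- matrix(NA_integer_, n_samp, n_mark)
  ref <- character(n_mark)
  alt <- character(n_mark)
  for (j in seq_len(n_mark)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(unique(obs[!is.na(obs)]))
    if (length(alleles) > 2) {
      stop(sprintf("marker %s has >2 alleles", map$marker_id[j]))
    }
    ref[j] <- if (length(alleles) >= 1) alleles[1] else "A"
    alt[j] <- if (length(alleles) == 2) alleles[2] else ref[j]
    calls[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
  }
  rownames(calls) <- sample_id
  map$a1 <- ref
  map$a2 <- alt
  gt <- orient_to_minor(as_geno_table(calls, map))

  phenotype <- dplyr::case_match(pheno_code,
    "2" ~ "affected", "1" ~ "unaffected", .default = "unknown")
  list(
    genotypes = gt,
    samples = tibble::tibble(
      sample_id = sample_id, phenotype = phenotype,
      breed = NA_character_, role = NA_character_
    )
  )
}

#' Write a genotype tibble as a plink-text PED/MAP pair
#'
#' @param gt wide genotype tibble
#' @param samples sample table supplying the PED phenotype column
#' @param ped_path,map_path output paths
#' @return invisibly, the two paths
#' @export
write_ped_map <- function(gt, samples, ped_path, map_path) {
  validate_marker_map(gt)
  ids <- sample_cols(gt)
  ph <- samples$phenotype[match(ids, samples$sample_id)]
  code <- dplyr::case_match(ph, "affected" ~ "2", "unaffected" ~ "1", .default = "0")
  writeLines(
    sprintf("%s\t%s\t0\t%d", gt$chrom, gt$marker_id, gt$pos),
    map_path
  )
  m <- geno_matrix(gt)
  lines <- vapply(seq_along(ids), function(i) {
    g <- m[i, ]
    one <- ifelse(is.na(g), "0", ifelse(g >= 1, gt$a2, gt$a1))
    two <- ifelse(is.na(g), "0", ifelse(g == 2, gt$a2, gt$a1))
    paste(c(ids[i], ids[i], "0", "0", "0", code[i], rbind(one, two)),
          collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}

#' Read / write the tab-separated sample metadata table
#'
#' Columns: sample_id, phenotype (affected/unaffected/unknown), breed, role
#' (case/obligate_carrier/control/population).
#'
#' @param path file path
#' @return tibble
#' @export
read_sample_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("sample_id", "phenotype", "breed", "role")
  if (!all(req %in% names(tab))) {
    stop("sample table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample_id in sample table")
  bad <- setdiff(unique(tab$phenotype), c("affected", "unaffected", "unknown"))
  if (length(bad) > 0) stop("unknown phenotype label: ", bad[1])
  tab
}

#' @rdname read_sample_table
#' @param samples sample tibble
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}
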