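#' Recessive segregation filter cascade
#'
#' The re-sequencing filter for a recessive disease: starting from a
#' multi-sample variant table, keep variants (1) inside the critical region,
#' (2) homozygous for the alternate allele in the sequenced case, (3)
#' heterozygous in the obligate carrier, and (4) not homozygous-alternate in
#' any control genome ("homozygous in a control" means hom-alt specifically,
#' the reference orientation of the cascade). A missing genotype at the
#' deciding sample never removes a variant: the variant is retained at that
#' stage and flagged for follow-up.
#'
#' @param variants wide variant tibble (see [read_vcf()])
#' @param case_id,carrier_id sample columns of the sequenced case and the
#'   obligate carrier (must differ)
#' @param control_ids sample columns of the control panel
#' @param region list(chrom, start, end) or "chrom:start-end"; 1-based
#'   inclusive
#' @param stages which stages to run, in fixed order (individually skippable)
#' @return list: `report` (tibble stage / n_input / n_surviving, in fixed
#'   order), `candidates` (surviving variant tibble), `flagged` (variant ids
#'   kept only because a deciding genotype was missing)
#' @export
segregation_filter <- function(variants, case_id, carrier_id, control_ids,
                               region,
                               stages = c("region", "case_hom", "carrier_het",
                                          "control_hom")) {
  if (identical(case_id, carrier_id)) stop("case and carrier must differ")
  need <- c(case_id, carrier_id, control_ids)
  missing_samp <- setdiff(need, names(variants))
  if (length(missing_samp) > 0) {
    stop("sample(s) not in variant table: ", paste(missing_samp, collapse = ", "))
  }
  region <- parse_region(region)
  cur <- variants
  flagged <- character(0)
  rows <- list()
  run <- function(stage, keep, flag = NULL) {
    n_in <- nrow(cur)
    cur <<- cur[keep, , drop = FALSE]
    if (!is.null(flag)) flagged <<- union(flagged, flag)
    rows[[stage]] <<- tibble::tibble(stage = stage, n_input = n_in,
                                     n_surviving = nrow(cur))
  }
  if ("region" %in% stages) {
    run("region", cur$chrom == region$chrom &
          cur$pos >= region$start & cur$pos <= region$end)
  }
  if ("case_hom" %in% stages) {
    g <- cur[[case_id]]
    run("case_hom", is.na(g) | g == 2L, cur$variant_id[is.na(g)])
  }
  if ("carrier_het" %in% stages) {
    g <- cur[[carrier_id]]
    run("carrier_het", is.na(g) | g == 1L, cur$variant_id[is.na(g)])
  }
  if ("control_hom" %in% stages) {
    if (length(control_ids) > 0 && nrow(cur) > 0) {
      cm <- as.matrix(as.data.frame(cur)[, control_ids, drop = FALSE])
      any_hom <- apply(cm, 1, function(x) any(!is.na(x) & x == 2L))
    } else {
      any_hom <- logical(nrow(cur))
    }
    run("control_hom", !any_hom)
  }
  list(report = dplyr::bind_rows(rows),
       candidates = cur,
       flagged = intersect(flagged, cur$variant_id))
}

parse_region <- function(region) {
  if (is.character(region) && length(region) == 1) {
    m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
    if (length(m) != 4) stop("malformed region string: ", region)
    region <- list(chrom = m[2],
                   start = as.numeric(gsub(",", "", m[3])),
                   end = as.numeric(gsub(",", "", m[4])))
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(region)))
  if (region$end < region$start) stop("region end precedes start")
  region
}

#' Restrict candidates to variants private to one breed
#'
#' Keeps variants whose alternate allele is observed (heterozygous or
#' homozygous) only in samples of the target breed. Missing genotypes carry
#' no allele observation. Every alt-allele carrier must have a breed label.
#'
#' @param variants wide variant tibble
#' @param samples sample table with `sample_id` and `breed` for every sample
#'   column of `variants`
#' @param target_breed the breed the variant must be private to
#' @return the subset of `variants` passing breed privacy
#' @export
breed_private <- function(variants, samples, target_breed) {
  ids <- sample_cols(variants)
  breed <- samples$breed[match(ids, samples$sample_id)]
  if (nrow(variants) == 0) return(variants)
  gm <- as.matrix(as.data.frame(variants)[, ids, drop = FALSE])
  keep <- vapply(seq_len(nrow(gm)), function(i) {
    carriers <- which(!is.na(gm[i, ]) & gm[i, ] >= 1L)
    b <- breed[carriers]
    if (anyNA(b)) stop("carrier sample without breed label")
    all(b == target_breed)
  }, TRUE)
  variants[keep, , drop = FALSE]
}

#' Genotype concordance with a recessive model
#'
#' Under a fully penetrant recessive model, affected individuals are expected
#' homozygous for the alternate allele and unaffected individuals anything
#' but. Discordant counts per cohort are therefore het + hom-ref for an
#' affected cohort and hom-alt for an unaffected cohort.
#'
#' @param counts tibble with columns variant_id, cohort, phenotype
#'   ("affected"/"unaffected"), n_hom_ref, n_het, n_hom_alt (missing calls
#'   excluded beforehand)
#' @param model only "recessive" is defined
#' @return `counts` with n_discordant and the rule applied
#' @export
genotype_concordance <- function(counts, model = "recessive") {
  model <- match.arg(model)
  cnt <- counts[, c("n_hom_ref", "n_het", "n_hom_alt")]
  if (any(as.matrix(cnt) < 0)) stop("genotype counts must be non-negative")
  dplyr::mutate(
    counts,
    n_discordant = ifelse(.data$phenotype == "affected",
                          .data$n_het + .data$n_hom_ref, .data$n_hom_alt),
    rule = ifelse(.data$phenotype == "affected",
                  "affected not hom-alt", "unaffected hom-alt")
  )
}

#' Tabulate genotype classes of selected variants across cohorts
#'
#' @param variants wide variant tibble
#' @param samples sample table with a `cohort` column (or `role` used as the
#'   cohort) and phenotype
#' @param variant_ids variants to tabulate
#' @return GenotypeCountTable-style tibble ready for [genotype_concordance()]
#' @export
genotype_count_table <- function(variants, samples, variant_ids) {
  cohort <- samples[["cohort"]] %||% samples[["role"]]
  sub <- variants[variants$variant_id %in% variant_ids, , drop = FALSE]
  ids <- intersect(sample_cols(sub), samples$sample_id)
  if (nrow(sub) == 0) {
    return(tibble::tibble(variant_id = character(), cohort = character(),
                          phenotype = character(), n_hom_ref = integer(),
                          n_het = integer(), n_hom_alt = integer()))
  }
  purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    g <- unlist(sub[i, ids])
    tibble::tibble(sample_id = ids, g = as.integer(g)) |>
      dplyr::left_join(
        tibble::tibble(sample_id = samples$sample_id, cohort = cohort,
                       phenotype = samples$phenotype),
        by = "sample_id") |>
      dplyr::filter(!is.na(.data$g)) |>
      dplyr::group_by(.data$cohort, .data$phenotype) |>
      dplyr::summarise(
        n_hom_ref = sum(.data$g == 0L), n_het = sum(.data$g == 1L),
        n_hom_alt = sum(.data$g == 2L), .groups = "drop") |>
      dplyr::mutate(variant_id = sub$variant_id[i], .before = 1)
  })
}
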