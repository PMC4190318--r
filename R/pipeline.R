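#' Run the full mapping study end-to-end
#'
#' Orchestrates the whole analysis on a simulated study: gene-drop simulation,
#' marker QC, allelic association scan (optionally with max-T permutation
#' significance), shared-autozygosity critical-interval mapping, the
#' recessive segregation filter cascade with breed-privacy stage, genotype
#' concordance of the final candidates over the sequenced panel, and an
#' allele-balance check of the candidate transcript. The run is a pure
#' function of its configuration: the same seed reproduces the report
#' exactly. One structured log line per stage reports input/output
#' cardinalities.
#'
#' @param config a [sim_config()]
#' @param qc a [qc_thresholds()]
#' @param roh a [roh_params()]
#' @param perm optional [perm_config()]; NULL skips permutation
#' @param ase_depth,ase_skew allele-balance simulation settings for the
#'   candidate transcript (balanced expression by default)
#' @param out_dir optional directory; when given, every intermediate artifact
#'   is written in its standard format (PED/MAP, sample TSV, association TSV,
#'   BED interval, VCF candidates, ASE TSV)
#' @param verbose print per-stage log lines (default TRUE)
#' @return a `study_report` list: `scan` (association tibble), `top_snp`,
#'   `interval`, `cascade` (filter report), `candidates`, `concordance`,
#'   `ase`, `discordant_animals`, `truth`
#' @export
run_study <- function(config = sim_config(), qc = qc_thresholds(),
                      roh = roh_params(), perm = NULL,
                      ase_depth = 100, ase_skew = 0.5,
                      out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))

  study <- simulate_study(config)
  say("simulate: %d samples x %d markers", length(sample_cols(study$genotypes)),
      nrow(study$genotypes))

  qcres <- qc_filter(study$genotypes, qc)
  say("qc: %d -> %d markers", nrow(study$genotypes), qcres$m)

  scan <- assoc_scan(qcres$genotypes, study$samples)
  if (!is.null(perm)) {
    pe <- maxt_permutation(qcres$genotypes, study$samples, perm)
    scan$p_emp <- pe$p_emp[match(scan$marker_id, pe$marker_id)]
  }
  top <- scan[which.min(scan$p_raw), ]
  say("gwas: top %s at %s:%d (chi2 = %.1f, lambda = %.2f)",
      top$marker_id, top$chrom, top$pos, top$chi2, attr(scan, "lambda"))

  case_ids <- study$samples$sample_id[study$samples$role == "case"]
  interval <- shared_autozygous_segment(study$genotypes, case_ids, roh)
  say("autozygosity: %s", if (nrow(interval) == 1)
    sprintf("interval %s:%d-%d (%d kb, %d shared SNPs)", interval$chrom,
            interval$left_bound_bp, interval$right_bound_bp,
            interval$length_kb, interval$n_shared_snps)
    else "no shared segment")

  wgs <- simulate_wgs_variants(config, study)
  region <- if (nrow(interval) == 1) {
    list(chrom = interval$chrom, start = interval$left_bound_bp,
         end = interval$right_bound_bp)
  } else {
    list(chrom = study$truth$causal_chrom,
         start = study$truth$shared_block$start_bp,
         end = study$truth$shared_block$end_bp)
  }
  fm_controls <- wgs$panel$sample_id[wgs$panel$role == "control"]
  cascade <- segregation_filter(wgs$variants, "wgs_case", "wgs_carrier",
                                fm_controls, region)
  final <- breed_private(cascade$candidates, wgs$panel, "FM")
  cascade$report <- dplyr::bind_rows(
    cascade$report,
    tibble::tibble(stage = "breed_private",
                   n_input = nrow(cascade$candidates),
                   n_surviving = nrow(final)))
  say("cascade: %s", paste(sprintf("%s %d->%d", cascade$report$stage,
                                   cascade$report$n_input,
                                   cascade$report$n_surviving),
                           collapse = ", "))

  counts <- genotype_count_table(wgs$variants, wgs$panel, final$variant_id)
  conc <- genotype_concordance(
    dplyr::filter(counts, .data$phenotype %in% c("affected", "unaffected")))

  ase_obs <- simulate_ase_counts(3, ase_depth, ase_skew,
                                 seed = config$seed + 2971L)
  ase <- allele_balance_test(ase_obs)
  say("ase: %d/%d sites balanced", sum(ase$verdict == "balanced"), nrow(ase))

  truth_dose <- study$truth$causal_dosage[study$samples$sample_id]
  discord <- study$samples[
    (truth_dose == 2L) != (study$samples$phenotype == "affected"), ]

  report <- structure(list(
    scan = scan, top_snp = top, interval = interval,
    cascade = cascade$report, candidates = final,
    flagged = cascade$flagged, concordance = conc, ase = ase,
    discordant_animals = discord, truth = study$truth,
    qc = qcres$report, config = config
  ), class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ped_map(study$genotypes, study$samples,
                  file.path(out_dir, "study.ped"), file.path(out_dir, "study.map"))
    write_sample_table(study$samples, file.path(out_dir, "samples.tsv"))
    readr::write_tsv(tibble::as_tibble(scan), file.path(out_dir, "assoc.tsv"),
                     progress = FALSE)
    if (nrow(interval) == 1) write_bed(interval, file.path(out_dir, "interval.bed"))
    write_vcf(wgs$variants, wgs$panel$sample_id, file.path(out_dir, "wgs.vcf"))
    if (nrow(final) > 0) {
      write_vcf(final, wgs$panel$sample_id, file.path(out_dir, "candidates.vcf"))
    }
    write_ase_counts(ase_obs, file.path(out_dir, "ase_counts.tsv"))
  }
  report
}

#' @method print study_report
#' @export
print.study_report <- function(x, ...) {
  cat("Recessive mapping study report\n")
  cat(sprintf("  top SNP: %s at %s:%d  chi2 = %.2f  p = %.3g (Bonferroni %.3g)\n",
              x$top_snp$marker_id, x$top_snp$chrom, x$top_snp$pos,
              x$top_snp$chi2, x$top_snp$p_raw, x$top_snp$p_bonf))
  cat(sprintf("  genomic inflation lambda = %.2f over %d markers\n",
              attr(x$scan, "lambda"), attr(x$scan, "m")))
  if (nrow(x$interval) == 1) {
    cat(sprintf("  critical interval: %s:%d-%d (%d kb, %d shared SNPs)\n",
                x$interval$chrom, x$interval$left_bound_bp,
                x$interval$right_bound_bp, x$interval$length_kb,
                x$interval$n_shared_snps))
  } else cat("  critical interval: none\n")
  cat("  filter cascade:\n")
  for (i in seq_len(nrow(x$cascade))) {
    cat(sprintf("    %-13s %5d -> %5d\n", x$cascade$stage[i],
                x$cascade$n_input[i], x$cascade$n_surviving[i]))
  }
  cat(sprintf("  final candidates: %s\n",
              paste(x$candidates$variant_id, collapse = ", ")))
  cat(sprintf("  discordant animals: %d\n", nrow(x$discordant_animals)))
  cat(sprintf("  ASE verdicts: %s\n", paste(x$ase$verdict, collapse = ", ")))
  invisible(x)
}
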