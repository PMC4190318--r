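#' Simulation settings for a gene-drop mapping study
#'
#' Defines the study design the simulator emulates: a handful of affected,
#' inbred individuals tracing back over a few generations to a single common
#' carrier ancestor, a same-breed control panel typed on the same array, and a
#' whole-genome-sequenced trio-plus-panel for segregation filtering. Defaults
#' follow the classical 5-case / 12-control array design with ~31 autosomes.
#'
#' @param n_cases number of affected, autozygous individuals (default 5)
#' @param n_controls number of array controls (default 12)
#' @param n_markers total array markers, spread evenly over chromosomes
#'   (default 5,000; use 38,394 for a full-array-scale run)
#' @param n_chromosomes number of autosomes (default 31)
#' @param chrom_length_bp physical length of each autosome (default 50 Mb)
#' @param founder_pool_size unrelated founders available as mates (default 30)
#' @param generations_to_founder integer range (min, max) of meioses
#'   separating a case from the common carrier ancestor (default 3--7)
#' @param causal_chrom,causal_pos_bp location of the planted recessive variant
#' @param penetrance probability an individual homozygous for the causal
#'   allele is labelled affected (default 1)
#' @param phenocopy_rate probability a non-homozygous individual is labelled
#'   affected anyway (default 0)
#' @param maf_range uniform range for founder marker minor-allele frequencies
#' @param missing_rate per-call genotyping failure rate (default 0.01)
#' @param n_carrier_controls how many array controls are heterozygous
#'   carriers descending from the founder lineage (default 3; never
#'   homozygous for the causal allele)
#' @param wgs_counts named list of decoy-variant class sizes for
#'   [simulate_wgs_variants()]: `case_hom_only` (homozygous in the case but
#'   not heterozygous in the carrier), `carrier_het_control_hom` (segregating
#'   in the trio but homozygous in at least one cross-breed control) and
#'   `segregating` (case-homozygous, carrier-heterozygous, never homozygous
#'   in any control; includes the causal variant, so must be >= 1)
#' @param n_outside_region decoy case-homozygous variants planted outside the
#'   autozygous region (exercise the region stage)
#' @param seed integer seed driving every random draw
#' @return a `sim_config` list
#' @export
sim_config <- function(n_cases = 5, n_controls = 12, n_markers = 5000,
                       n_chromosomes = 31, chrom_length_bp = 50e6,
                       founder_pool_size = 30,
                       generations_to_founder = c(3L, 7L),
                       causal_chrom = "20", causal_pos_bp = 25e6,
                       penetrance = 1, phenocopy_rate = 0,
                       maf_range = c(0.05, 0.5), missing_rate = 0.01,
                       n_carrier_controls = 3,
                       wgs_counts = list(case_hom_only = 49,
                                         carrier_het_control_hom = 13,
                                         segregating = 2),
                       n_outside_region = 20,
                       seed = 1L) {
  cfg <- list(
    n_cases = n_cases, n_controls = n_controls, n_markers = n_markers,
    n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
    founder_pool_size = founder_pool_size,
    generations_to_founder = as.integer(generations_to_founder),
    causal_chrom = as.character(causal_chrom), causal_pos_bp = causal_pos_bp,
    penetrance = penetrance, phenocopy_rate = phenocopy_rate,
    maf_range = maf_range, missing_rate = missing_rate,
    n_carrier_controls = n_carrier_controls,
    wgs_counts = wgs_counts, n_outside_region = n_outside_region,
    seed = as.integer(seed)
  )
  rates <- c(cfg$penetrance, cfg$phenocopy_rate, cfg$missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$penetrance <= 0) stop("penetrance must be in (0, 1]")
  if (!(cfg$causal_chrom %in% as.character(seq_len(cfg$n_chromosomes)))) {
    stop("causal_chrom outside the simulated genome")
  }
  if (cfg$causal_pos_bp < 1 || cfg$causal_pos_bp > cfg$chrom_length_bp) {
    stop("causal_pos_bp outside the simulated chromosome")
  }
  if (cfg$generations_to_founder[1] < 2) {
    stop("cases need at least 2 generations to the common ancestor")
  }
  if (cfg$wgs_counts$segregating < 1) {
    stop("wgs_counts$segregating must include the causal variant (>= 1)")
  }
  if (cfg$n_carrier_controls > cfg$n_controls) {
    stop("n_carrier_controls exceeds n_controls")
  }
  if (cfg$founder_pool_size < 3) stop("founder pool too small to form matings")
  structure(cfg, class = "sim_config")
}

# --- haplotype machinery -----------------------------------------------------
# A haplotype on one chromosome is a pair of parallel vectors: `ends` (bp,
# last element = chromosome length) and `ids` (founder-haplotype id of each
# segment). An individual is list(h1, h2), each a list over chromosomes.

.hap_founder <- function(id, n_chrom, len) {
  one <- lapply(seq_len(n_chrom), function(c) list(ends = len, ids = id))
  one
}

.hap_id_at <- function(hap_chrom, pos) {
  hap_chrom$ids[findInterval(pos - 0.5, hap_chrom$ends) + 1L]
}

.splice <- function(hA, hB, cuts, first) {
  bounds <- c(0, cuts, hA$ends[length(hA$ends)])
  ends <- numeric(0)
  ids <- integer(0)
  src <- first
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k]; hi <- bounds[k + 1L]
    if (hi > lo) {
      h <- if (src == 1L) hA else hB
      i1 <- sum(h$ends <= lo) + 1L
      i2 <- sum(h$ends < hi) + 1L
      e <- h$ends[i1:i2]
      e[length(e)] <- hi
      ends <- c(ends, e)
      ids <- c(ids, h$ids[i1:i2])
    }
    src <- 3L - src
  }
  if (length(ids) > 1L) {
    keep <- c(ids[-1L] != ids[-length(ids)], TRUE)
    ends <- ends[keep]; ids <- ids[keep]
  }
  list(ends = ends, ids = ids)
}

# One meiosis. Crossover count per chromosome is Poisson with mean equal to
# the genetic length in Morgans at a fixed 1 cM/Mb (Haldane, no interference);
# breakpoints are uniform. When `force` is given, the output gamete is
# conditioned to carry founder-haplotype id 1 (the carrier haplotype) at the
# forced position -- conditioned gene drop down the known descent path.
.meiosis <- function(ind, n_chrom, len, force_chrom = NA_integer_,
                     force_pos = NA_real_) {
  morgans <- len * 1e-8        # 1 cM/Mb
  lapply(seq_len(n_chrom), function(c) {
    n_x <- stats::rpois(1, morgans)
    cuts <- if (n_x > 0) sort(stats::runif(n_x, 0, len)) else numeric(0)
    first <- sample(1:2, 1)
    if (!is.na(force_chrom) && c == force_chrom) {
      carrier_src <- if (.hap_id_at(ind$h1[[c]], force_pos) == 1L) 1L
                     else if (.hap_id_at(ind$h2[[c]], force_pos) == 1L) 2L
                     else stop("conditioned drop: parent lacks the carrier haplotype")
      seg <- findInterval(force_pos, cuts) + 1L   # which inter-cut interval
      first <- if (seg %% 2L == 1L) carrier_src else 3L - carrier_src
    }
    .splice(ind$h1[[c]], ind$h2[[c]], cuts, first)
  })
}

.mate <- function(gam1, gam2) list(h1 = gam1, h2 = gam2)

#' Simulate a complete recessive-disease mapping study
#'
#' Gene-drop simulation with founder-haplotype tracking. One founder carries
#' the causal recessive allele on a designated haplotype; each case descends
#' from that founder through two independent lineages (sire and dam side) and
#' the transmission of the carrier haplotype at the causal locus is
#' conditioned along those paths, so every case is autozygous for a founder
#' segment spanning the causal position. Controls are founder offspring, with
#' a configurable number of heterozygous carrier-lineage animals (never
#' homozygous for the causal allele). Because the drop is conditioned, any
#' configuration accepted by [sim_config()] is feasible by construction.
#'
#' @param config a [sim_config()] object
#' @return a `sim_study` list with elements `genotypes` (wide genotype
#'   tibble), `samples` (sample table), `pedigree`, and `truth` (causal locus,
#'   per-case haplotype-level autozygous segment bounds, their intersection,
#'   and the marker-level shared block with its flanking markers)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chrom <- config$n_chromosomes
  len <- config$chrom_length_bp
  ci <- as.integer(config$causal_chrom)
  cpos <- config$causal_pos_bp

  # marker map: markers spread evenly over chromosomes, uniform positions
  per_chrom <- diff(round(seq(0, config$n_markers, length.out = n_chrom + 1)))
  map <- dplyr::bind_rows(lapply(seq_len(n_chrom), function(c) {
    tibble::tibble(
      chrom = as.character(c),
      pos = sort(sample.int(len, per_chrom[c]))
    )
  }))
  map$marker_id <- sprintf("snp_%05d", seq_len(nrow(map)))
  maf <- stats::runif(nrow(map), config$maf_range[1], config$maf_range[2])

  # founder haplotype alleles: 1 = minor allele
  n_f <- config$founder_pool_size
  H <- matrix(stats::rbinom(2L * n_f * nrow(map), 1L, rep(maf, each = 2L * n_f)),
              nrow = 2L * n_f)

  founders <- lapply(seq_len(n_f), function(k) {
    .mate(.hap_founder(2L * k - 1L, n_chrom, len),
          .hap_founder(2L * k, n_chrom, len))
  })
  # founder 1 is the common ancestor; haplotype id 1 carries the causal allele
  ancestor <- founders[[1]]
  mate_pool <- 2:n_f

  ped <- tibble::tibble(individual = character(), sire = character(),
                        dam = character(), generation = integer())
  add_ped <- function(id, sire, dam, gen) {
    ped <<- dplyr::bind_rows(ped, tibble::tibble(
      individual = id, sire = sire, dam = dam, generation = as.integer(gen)))
  }
  add_ped("founder_1", NA, NA, 0L)

  # one conditioned descent lineage of `g` meioses from the ancestor;
  # returns the terminal individual (a parent of a case), which is
  # heterozygous for the carrier haplotype at the causal locus
  lineage_counter <- 0L
  descend <- function(g, tag) {
    cur <- ancestor
    cur_id <- "founder_1"
    for (step in seq_len(g - 1L)) {
      lineage_counter <<- lineage_counter + 1L
      mate_k <- sample(mate_pool, 1)
      forced <- .meiosis(cur, n_chrom, len, ci, cpos)
      free <- .meiosis(founders[[mate_k]], n_chrom, len)
      child_id <- sprintf("anc_%s_%02d", tag, lineage_counter)
      add_ped(child_id, cur_id, sprintf("founder_%d", mate_k), step)
      cur <- .mate(forced, free)
      cur_id <- child_id
    }
    list(ind = cur, id = cur_id)
  }

  gen_rng <- config$generations_to_founder
  inds <- list()
  case_ids <- sprintf("case_%02d", seq_len(config$n_cases))
  for (i in seq_len(config$n_cases)) {
    gs <- sample(seq(gen_rng[1], gen_rng[2]), 1)
    gd <- sample(seq(gen_rng[1], gen_rng[2]), 1)
    sire <- descend(gs, sprintf("s%02d", i))
    dam <- descend(gd, sprintf("d%02d", i))
    child <- .mate(.meiosis(sire$ind, n_chrom, len, ci, cpos),
                   .meiosis(dam$ind, n_chrom, len, ci, cpos))
    add_ped(case_ids[i], sire$id, dam$id, max(gs, gd))
    inds[[case_ids[i]]] <- child
  }

  ctrl_ids <- sprintf("ctrl_%02d", seq_len(config$n_controls))
  for (i in seq_len(config$n_controls)) {
    if (i <= config$n_carrier_controls) {
      g <- sample(seq(gen_rng[1], gen_rng[2]), 1)
      par <- descend(g, sprintf("c%02d", i))
      mate_k <- sample(mate_pool, 1)
      child <- .mate(.meiosis(par$ind, n_chrom, len, ci, cpos),
                     .meiosis(founders[[mate_k]], n_chrom, len))
      add_ped(ctrl_ids[i], par$id, sprintf("founder_%d", mate_k), g)
    } else {
      ks <- sample(mate_pool, 2)
      child <- .mate(.meiosis(founders[[ks[1]]], n_chrom, len),
                     .meiosis(founders[[ks[2]]], n_chrom, len))
      add_ped(ctrl_ids[i], sprintf("founder_%d", ks[1]),
              sprintf("founder_%d", ks[2]), 1L)
    }
    inds[[ctrl_ids[i]]] <- child
  }

  study_ids <- c(case_ids, ctrl_ids)
  chrom_of <- as.integer(map$chrom)
  calls <- matrix(NA_integer_, length(study_ids), nrow(map),
                  dimnames = list(study_ids, NULL))
  causal_dosage <- integer(length(study_ids))
  ibd <- vector("list", length(study_ids))
  for (s in seq_along(study_ids)) {
    ind <- inds[[study_ids[s]]]
    al <- matrix(0L, 2L, nrow(map))
    for (c in seq_len(n_chrom)) {
      j <- which(chrom_of == c)
      if (length(j) == 0) next
      h1 <- ind$h1[[c]]; h2 <- ind$h2[[c]]
      id1 <- h1$ids[findInterval(map$pos[j] - 0.5, h1$ends) + 1L]
      id2 <- h2$ids[findInterval(map$pos[j] - 0.5, h2$ends) + 1L]
      al[1L, j] <- H[cbind(id1, j)]
      al[2L, j] <- H[cbind(id2, j)]
    }
    calls[s, ] <- al[1L, ] + al[2L, ]
    h1c <- ind$h1[[ci]]; h2c <- ind$h2[[ci]]
    causal_dosage[s] <- (.hap_id_at(h1c, cpos) == 1L) +
      (.hap_id_at(h2c, cpos) == 1L)
    ibd[[s]] <- .ibd_segment(h1c, h2c, cpos)
  }

  true_calls <- calls
  if (config$missing_rate > 0) {
    calls[stats::runif(length(calls)) < config$missing_rate] <- NA_integer_
  }

  # phenotype from causal dosage under the penetrance / phenocopy model
  hom <- causal_dosage == 2L
  affected <- ifelse(hom, stats::runif(length(hom)) < config$penetrance,
                     stats::runif(length(hom)) < config$phenocopy_rate)

  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, nrow(map), replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), "")
  map$a1 <- a1
  map$a2 <- unname(a2)
  gt <- as_geno_table(calls, map[, c("marker_id", "chrom", "pos", "a1", "a2")])

  samples <- tibble::tibble(
    sample_id = study_ids,
    phenotype = ifelse(affected, "affected", "unaffected"),
    breed = "FM",
    role = rep(c("case", "control"), c(config$n_cases, config$n_controls))
  )

  truth_case <- tibble::tibble(
    sample_id = case_ids,
    start_bp = vapply(seq_len(config$n_cases), function(i) ibd[[i]][1], 0),
    end_bp = vapply(seq_len(config$n_cases), function(i) ibd[[i]][2], 0)
  )
  shared_ibd <- c(max(truth_case$start_bp), min(truth_case$end_bp))
  block <- .marker_shared_block(
    true_calls[seq_len(config$n_cases), , drop = FALSE], map, ci, cpos)

  structure(list(
    genotypes = gt,
    samples = samples,
    pedigree = ped,
    truth = list(
      causal_chrom = config$causal_chrom,
      causal_pos_bp = cpos,
      causal_dosage = stats::setNames(causal_dosage, study_ids),
      case_segments = truth_case,
      shared_ibd_bp = shared_ibd,
      shared_block = block
    ),
    config = config
  ), class = "sim_study")
}

# haplotype-level autozygous segment of one individual around the causal
# position: intersection of the two homologs' carrier (id 1) segments
.ibd_segment <- function(h1, h2, pos) {
  seg <- function(h) {
    k <- findInterval(pos - 0.5, h$ends) + 1L
    if (h$ids[k] != 1L) return(c(NA_real_, NA_real_))
    c(if (k == 1L) 1 else h$ends[k - 1L] + 1, h$ends[k])
  }
  s1 <- seg(h1); s2 <- seg(h2)
  c(max(s1[1], s2[1]), min(s1[2], s2[2]))
}

# marker-level ground truth: the maximal run of markers around the causal
# position at which all cases are homozygous for the same allele (before
# missingness is applied); its flanking markers break sharing by construction
.marker_shared_block <- function(case_calls, map, ci, cpos) {
  j <- which(as.integer(map$chrom) == ci)
  if (length(j) == 0) return(NULL)
  shr <- apply(case_calls[, j, drop = FALSE], 2, function(g) {
    all(g == 0L) || all(g == 2L)
  })
  k0 <- findInterval(cpos, map$pos[j])
  anchor <- if (k0 >= 1 && shr[k0]) k0
            else if (k0 < length(j) && shr[k0 + 1]) k0 + 1
            else return(NULL)
  lo <- anchor; while (lo > 1 && shr[lo - 1]) lo <- lo - 1
  hi <- anchor; while (hi < length(shr) && shr[hi + 1]) hi <- hi + 1
  list(
    chrom = as.character(ci),
    first_marker = map$marker_id[j[lo]],
    last_marker = map$marker_id[j[hi]],
    start_bp = map$pos[j[lo]],
    end_bp = map$pos[j[hi]],
    n_markers = hi - lo + 1L,
    flank_left_bp = if (lo > 1) map$pos[j[lo - 1]] else NA_integer_,
    flank_right_bp = if (hi < length(j)) map$pos[j[hi + 1]] else NA_integer_
  )
}

#' Simulate the whole-genome variant table for segregation filtering
#'
#' Plants variant classes with known filter fate inside (and outside) the true
#' autozygous region of a simulated study: variants homozygous in the
#' sequenced case but not heterozygous in the carrier; variants segregating in
#' the trio but homozygous in a cross-breed control; and fully segregating
#' variants never homozygous in any control, exactly one of which -- the
#' causal variant -- is additionally absent from every non-target-breed
#' sample. The sequenced panel comprises the first case, one obligate carrier
#' (a parent of that case) and 46 controls (28 same-breed, 18 cross-breed).
#'
#' @param config the [sim_config()] used for the study
#' @param study a `sim_study` from [simulate_study()]
#' @param adversarial_control_hom if TRUE, flags the causal variant homozygous
#'   in one same-breed control -- a negative control that must make the filter
#'   cascade lose the causal variant
#' @return list with `variants` (wide variant tibble), `panel` (sample table
#'   for the sequenced samples) and `causal_variant_id`
#' @export
simulate_wgs_variants <- function(config, study,
                                  adversarial_control_hom = FALSE) {
  stopifnot(inherits(study, "sim_study"))
  set.seed(config$seed + 104729L)  # independent stream from the study drop
  block <- study$truth$shared_block
  if (is.null(block)) stop("study has no shared autozygous block to plant into")
  n_fm <- 28L; n_ob <- 18L
  fm_ids <- sprintf("wgs_fm_%02d", seq_len(n_fm))
  ob_ids <- sprintf("wgs_ob_%02d", seq_len(n_ob))
  case_id <- "wgs_case"
  carrier_id <- "wgs_carrier"
  panel_ids <- c(case_id, carrier_id, fm_ids, ob_ids)
  ctrl_ids <- c(fm_ids, ob_ids)

  wc <- config$wgs_counts
  n_a <- wc$case_hom_only
  n_b <- wc$carrier_het_control_hom
  n_c <- wc$segregating
  n_in <- n_a + n_b + n_c
  span <- block$end_bp - block$start_bp - 2L
  if (span < n_in) stop("variant class counts exceed positions available in region")

  pool <- setdiff(seq(block$start_bp + 1L, block$end_bp - 1L),
                  study$truth$causal_pos_bp)
  pos_in <- sort(c(sample(pool, n_in - 1L), study$truth$causal_pos_bp))
  cls <- rep(c("a", "b", "c"), c(n_a, n_b, n_c))
  cls <- sample(cls)
  causal_k <- which(pos_in == study$truth$causal_pos_bp)[1]
  # make sure the causal position carries a fully segregating variant
  swap <- which(cls == "c")[1]
  cls[c(causal_k, swap)] <- cls[c(swap, causal_k)]
  cls[causal_k] <- "c"
  is_causal <- seq_len(n_in) == causal_k

  n_out <- config$n_outside_region
  other_chrom <- setdiff(as.character(seq_len(config$n_chromosomes)),
                         config$causal_chrom)
  pos_out <- sample.int(config$chrom_length_bp, n_out)
  chrom_out <- sample(other_chrom, n_out, replace = TRUE)

  n_tot <- n_in + n_out
  g <- matrix(0L, n_tot, length(panel_ids),
              dimnames = list(NULL, panel_ids))
  g[, case_id] <- 2L
  for (k in seq_len(n_in)) {
    ctrls <- stats::rbinom(length(ctrl_ids), 2L, 0.15)
    if (cls[k] == "a") {
      g[k, carrier_id] <- sample(c(0L, 2L), 1)
      if (!any(ctrls == 2L)) ctrls[sample(length(ctrls), 1)] <- 2L
    } else if (cls[k] == "b") {
      g[k, carrier_id] <- 1L
      ctrls <- pmin(ctrls, 1L)
      ctrls[n_fm + sample(n_ob, 1)] <- 2L
    } else {
      g[k, carrier_id] <- 1L
      ctrls <- pmin(ctrls, 1L)  # never homozygous in any control
      if (is_causal[k]) {
        ctrls[(n_fm + 1):(n_fm + n_ob)] <- 0L   # breed-private
      } else {
        # seen heterozygous outside the target breed: fails breed privacy
        ctrls[n_fm + sample(n_ob, 1)] <- 1L
      }
    }
    g[k, ctrl_ids] <- ctrls
  }
  if (n_out > 0) {
    g[n_in + seq_len(n_out), carrier_id] <-
      sample(0:2, n_out, replace = TRUE)
    g[n_in + seq_len(n_out), ctrl_ids] <-
      stats::rbinom(n_out * length(ctrl_ids), 2L, 0.2)
  }
  if (adversarial_control_hom) g[causal_k, fm_ids[1]] <- 2L

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_tot, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  variants <- tibble::tibble(
    variant_id = sprintf("var_%05d", seq_len(n_tot)),
    chrom = c(rep(block$chrom, n_in), chrom_out),
    pos = c(pos_in, pos_out),
    ref = ref,
    alt = unname(alt)
  )
  variants <- dplyr::bind_cols(
    variants, tibble::as_tibble(g, .name_repair = "minimal"))
  ord <- order(as.integer(variants$chrom), variants$pos)
  variants <- variants[ord, ]
  causal_variant_id <- variants$variant_id[variants$pos == study$truth$causal_pos_bp &
                                           variants$chrom == block$chrom][1]

  breeds <- c("FM", "FM", rep("FM", n_fm),
              sample(c("WB", "TB", "AR", "NF"), n_ob, replace = TRUE))
  panel <- tibble::tibble(
    sample_id = panel_ids,
    phenotype = c("affected", "unaffected", rep("unaffected", n_fm + n_ob)),
    breed = breeds,
    role = c("case", "obligate_carrier", rep("control", n_fm + n_ob))
  )
  list(variants = variants, panel = panel,
       causal_variant_id = causal_variant_id)
}

#' Simulate allele-count observations for allele-specific expression
#'
#' Genomic-DNA counts at a heterozygous site are drawn Binomial(depth, 0.5);
#' cDNA counts Binomial(depth, skew). skew = 0.5 is balanced expression; skew
#' far from 0.5 emulates allele-specific loss of transcript (for example
#' nonsense-mediated decay of one allele).
#'
#' @param n_sites number of assayed heterozygous sites
#' @param depth sequencing/peak depth per site (>= 1)
#' @param skew cDNA alternate-allele proportion, in (0, 1)
#' @param seed integer seed
#' @return tibble: site, gdna_ref, gdna_alt, cdna_ref, cdna_alt
#' @export
simulate_ase_counts <- function(n_sites, depth, skew = 0.5, seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  if (skew <= 0 || skew >= 1) stop("skew must be in (0, 1)")
  set.seed(as.integer(seed))
  ga <- stats::rbinom(n_sites, depth, 0.5)
  ca <- stats::rbinom(n_sites, depth, skew)
  tibble::tibble(
    site = sprintf("site_%03d", seq_len(n_sites)),
    gdna_ref = depth - ga, gdna_alt = ga,
    cdna_ref = depth - ca, cdna_alt = ca
  )
}

#' Simulate unrelated null genotypes (no causal locus, no pedigree)
#'
#' Independent Hardy-Weinberg draws at every marker for every sample, used to
#' calibrate the association scan (genomic inflation near 1, family-wise
#' error control) in the absence of any true signal or relatedness.
#'
#' @inheritParams sim_config
#' @param n_samples samples to draw; the first `n_cases` are labelled affected
#' @return list with `genotypes` and `samples` as in [simulate_study()]
#' @export
simulate_null_genotypes <- function(n_samples = 17, n_cases = 5,
                                    n_markers = 5000, n_chromosomes = 31,
                                    chrom_length_bp = 50e6,
                                    maf_range = c(0.05, 0.5), seed = 1L) {
  set.seed(as.integer(seed))
  per_chrom <- diff(round(seq(0, n_markers, length.out = n_chromosomes + 1)))
  map <- dplyr::bind_rows(lapply(seq_len(n_chromosomes), function(c) {
    tibble::tibble(chrom = as.character(c),
                   pos = sort(sample.int(chrom_length_bp, per_chrom[c])))
  }))
  map$marker_id <- sprintf("snp_%05d", seq_len(nrow(map)))
  maf <- stats::runif(nrow(map), maf_range[1], maf_range[2])
  calls <- matrix(
    stats::rbinom(n_samples * nrow(map), 2L, rep(maf, each = n_samples)),
    nrow = n_samples)
  ids <- sprintf("s_%02d", seq_len(n_samples))
  rownames(calls) <- ids
  bases <- c("A", "C", "G", "T")
  map$a1 <- sample(bases, nrow(map), replace = TRUE)
  map$a2 <- vapply(map$a1, function(b) sample(setdiff(bases, b), 1), "")
  gt <- as_geno_table(calls, map[, c("marker_id", "chrom", "pos", "a1", "a2")])
  samples <- tibble::tibble(
    sample_id = ids,
    phenotype = rep(c("affected", "unaffected"), c(n_cases, n_samples - n_cases)),
    breed = "FM",
    role = rep(c("case", "control"), c(n_cases, n_samples - n_cases))
  )
  list(genotypes = gt, samples = samples)
}
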