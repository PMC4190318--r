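---
title: "Mapping a lethal recessive variant by autozygosity: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a lethal recessive variant by autozygosity: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recmapr)
```

## The study design recmapr models

recmapr implements the classical pipeline for mapping a monogenic autosomal
recessive disease in a closed animal population: a handful of affected,
inbred individuals — all tracing back over a few generations to one common
carrier ancestor — and a small same-breed control panel are typed on a SNP
array. Because each affected animal received two copies of the ancestor's
chromosome segment around the causal variant, all cases are *autozygous*
(homozygous identical-by-descent) for a shared founder haplotype there. The
pipeline exploits this three ways:

1. **Allelic association.** At each marker, the 2x2 table of allele counts
   in cases versus controls is tested with a Pearson chi-square (1 df,
   *no* continuity correction). With $n_\mathrm{case}$ cases and
   $n_\mathrm{ctrl}$ controls the statistic is bounded by the total allele
   count $N = 2(n_\mathrm{case}+n_\mathrm{ctrl})$, attained exactly at
   complete separation; for 5 cases and 12 controls that bound is
   $\chi^2 = 34$, with upper-tail $p = 5.5\times10^{-9}$. The continuity
   correction is omitted deliberately: it destroys this correspondence and
   is inappropriate for the permutation-calibrated inference used here.
   Genome-wide significance comes from two directions: Bonferroni
   ($p_\mathrm{Bonf} = \min(1, m\,p)$ over the $m$ retained markers) and
   max-T permutation — case/control labels are shuffled (case count fixed),
   the genome-wide maximum statistic recorded per permutation, and the
   empirical p-value at a marker is $(r+1)/(R+1)$ with $r$ the number of
   permutation maxima at or above the observed statistic. The add-one
   estimator never reports zero and is positively biased, which is the safe
   direction. Ties count as exceedances. The genomic inflation factor
   $\lambda = \mathrm{median}(\chi^2)/0.4549$ (the 0.4549 being the median
   of $\chi^2_1$) is reported because closely related cases inflate the
   test; in this design values near 1.3 are expected and are a property of
   the sampling, not an error.

2. **Autozygosity mapping.** Runs of homozygosity (ROH) are detected per
   individual by direct run scanning: maximal stretches of non-missing
   homozygous calls tolerating at most `max_het` heterozygous calls, with
   missing calls passing silently (they count toward neither the SNP total
   nor the heterozygote allowance). Runs need `min_snps` homozygous calls
   (default 25) over `min_length_kb` (default 500) to qualify — thresholds
   mapped one-to-one from the sliding-window tool traditionally used, whose
   window machinery is an approximation detail we do not reproduce. The
   shared segment is the intersection of all cases' qualifying ROH,
   refined marker-by-marker: a marker counts as *shared* when every case is
   homozygous for the same allele (at least `match_frac` of pairwise
   comparisons identical); a heterozygote or an above-tolerance allele
   conflict breaks the run; a missing call is compatible but uncounted. The
   length and SNP-count thresholds act on the per-individual runs only —
   the cross-case intersection is as long as it is, exactly as in the
   grouping behaviour of the original tool. The reported *critical
   interval* is closed at the nearest flanking markers at which sharing
   breaks, matching how such intervals are quoted (e.g. a 952-kb interval
   between flanking heterozygous markers at 49,164,218 and 50,115,936).

3. **Segregation filtering.** Whole-genome variant calls for one case, one
   obligate carrier, and a control panel are pushed through a fixed
   cascade: restrict to the critical interval, keep case-homozygous
   variants, keep carrier-heterozygous variants, drop variants homozygous
   for the alternate allele in any control, and finally keep variants whose
   alternate allele is private to the target breed. "Homozygous in a
   control" means hom-alt specifically. A missing genotype at the deciding
   sample never removes a variant — it is kept and flagged, mirroring how
   ambiguous calls are resolved by targeted re-genotyping rather than
   discarded. Candidate variants are then scored for cohort concordance
   under the recessive model (affected expected hom-alt, unaffected
   expected anything else), and transcript-level arithmetic converts
   between genomic, cDNA and protein coordinates (c.1 = A of the initiator
   ATG; residue = ceiling(cdna/3); minus-strand genes complement at the
   annotation boundary only).

A quantitative allele-balance check rounds the pipeline off: at a
heterozygous site, genomic-DNA and cDNA allele counts form a 2x2 table
tested with a two-sided Fisher exact test; the verdict is *balanced* iff
p > alpha (default 0.05) **and** the fold change is below a guard (default
1.5). The fold change is the largest cDNA-versus-gDNA ratio of either
allele's fraction — taking the maximum over both alleles makes the
statistic invariant to which allele is called "ref", which an alt-only
ratio is not. Balance at a nonsense- or splice-suspect site argues against
transcript-level loss such as nonsense-mediated decay.

## What the simulator emulates — and what it does not

`simulate_study()` performs a conditioned gene drop. One founder haplotype
carries the causal allele; each case descends from that founder through two
independent lineages whose length is drawn uniformly from
`generations_to_founder` (default 3–7 meioses). At every meiosis on those
paths the gamete is conditioned to transmit the carrier haplotype at the
causal position; recombination elsewhere is free, with crossover counts
Poisson at a fixed 1 cM/Mb (Haldane, no interference) and uniform breakpoint
placement. This guarantees every case is autozygous across a founder segment
covering the causal position — so any accepted configuration is feasible by
construction — while the segment's extent erodes realistically with each
meiosis. Controls are founder offspring; a configurable few are
heterozygous carrier-lineage animals (never hom-alt). Phenotypes follow the
genotype through a penetrance/phenocopy model. Defaults mirror the study
design this package is built around: 5 cases, 12 controls, 31 autosomes of
50 Mb, 5,000 markers with founder MAF uniform on [0.05, 0.5], 1% missing
calls, full penetrance. The 5,000-marker default keeps a full pipeline run
in seconds; `n_markers = 38394` reproduces the informative-marker density
of a real 65k array after QC and is the scale at which autozygosity mapping
is actually powered (see below).

The simulator tracks founder-haplotype identity through every meiosis, so
ground truth is exact: per-case IBD segment bounds, their intersection, and
the marker-level shared block with its flanking sharing-breakers.
`simulate_wgs_variants()` plants decoy variant classes with known filter
fate inside the autozygous region — case-homozygous-only (default 49),
trio-segregating but control-homozygous (13), and fully segregating (2, of
which exactly one, the causal, is breed-private) — giving a
64 → 15 → 2 → 1 cascade, a desk-scale echo of the four-stage structure
reported for real genomes. An adversarial switch flags the causal
homozygous in one control, and the cascade must then lose it; tests assert
both directions.

What the simulator does **not** model: linkage disequilibrium beyond descent
from the founder pool, genotyping error (missingness only), coalescent
population structure, X/Y chromosomes, pedigree loops (lineages share only
the single common ancestor), and sequencing-error or coverage models for
the WGS table. Passing tests therefore demonstrate the pipeline's logic and
calibration under idealised inheritance, not robustness to array artefacts.

## Numerical choices

* **HWE exact test** uses the probability-ordering two-sided convention —
  the p-value sums conditional probabilities of heterozygote counts no more
  probable than observed (with a 1e-10 log-scale tie tolerance);
  monomorphic markers return 1. QC applies call-rate, MAF and HWE rules in
  that fixed order, attributing each removed marker to the first failing
  rule; call-rate denominators count all samples.
* **Genomic inflation with 17 samples is discrete.** The allelic chi-square
  over 34 alleles takes isolated values; the per-replicate median sits on
  an atom boundary and flips between λ = 1.00 and λ = 1.25 across null
  replicates. Calibration is therefore assessed on the pooled per-marker
  statistics of 10 null replicates, where λ is stable at 1.001. This is a
  property of the median at this sample size, not of the implementation.
* **Permutation streaming.** Label shuffles are processed in fixed chunks
  of 2,000 (never materialising all permutations), and the chunk size is
  part of the deterministic stream: the same seed gives identical results.
* **Interval rounding** is half-up to the kb (951,718 bp → 952 kb).
* **Tie-breaks.** Among equally long shared segments the first in genome
  order wins; permutation ties count as exceedances (the conservative
  side).
* **Degenerate inputs.** Association tables with an empty margin score
  chi-square 0, p 1; QC removing every marker warns and returns an empty
  set; an empty filter region yields an empty report, not an error.

## Design decisions that were genuinely open

* **Direct run-scan ROH.** The traditional tool's sliding window is an
  implementation heuristic; the published confirmation of the mapped
  segment was visual inspection of genotypes. We scan runs directly and
  map the thresholds one-to-one.
* **Threshold placement for shared segments.** Applying the SNP-count and
  length thresholds to the cross-case intersection (instead of only to
  per-case runs) makes desk-scale recovery impossible whenever the
  intersection is legitimately short; per-case placement matches the
  original tool's grouping semantics and is what we implement.
* **Marker-level strict matching.** A marker at which any case is
  heterozygous, or cases carry opposite homozygotes, breaks the shared run.
  This is the strictest defensible reading of "shared identical alleles
  over N consecutive markers" and makes the reported block count exact.
* **Array allele coding** is not specified by array vendors consistently;
  genotypes are re-oriented at load time so code 2 counts the cohort minor
  allele, and every statistic downstream is invariant to the original
  labelling (asserted by test).
* **ASE quantification** for electropherogram-style peak comparisons has no
  canonical statistic; a Fisher exact 2x2 with a symmetric fold-change
  guard is the minimal quantitative surrogate, both thresholds exposed.

## Known limitations

* At the 5,000-marker desk density (~3 markers/Mb) a shared autozygous
  block is often represented by fewer than five markers; detection there
  says more about map density than about the method. The package's own
  recovery experiments run at the 38,394-marker scale.
* Even at full density, two genuine phenomena cap recovery below 100%:
  the intersection of ten conditioned transmissions is heavy-tailed small
  (a case's own causal ROH can fall below the 25-SNP rule), and
  recombination mosaics can place the carrier haplotype back on both
  homologs of every case at a second locus, creating a secondary shared
  segment that can out-length the causal one. Both would defeat the
  original analysis equally; the package reports what the data support.
* The permutation test shuffles labels only; it does not correct for the
  relatedness that inflates λ, and the empirical threshold inherits the
  case-configuration granularity (the minimum attainable genome-wide p is
  $1/\binom{17}{5}$ for the default design).

## Problem sizes used in the test suite

Unit tests run on fixtures of tens of markers and small simulated studies
(5,000 markers). Calibration checks pool ten 17-sample null replicates at
5,000 markers; permutation consistency uses 200,000 shuffles over 1,000
markers; recovery uses 100 replicates at the 38,394-marker scale. These
sizes were chosen so the whole suite completes in well under half an hour
on one core while keeping every Monte-Carlo tolerance at three standard
errors or better.
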