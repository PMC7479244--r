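---
title: "Differential methylation analysis of RRBS count data with rrbsmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation analysis of RRBS count data with rrbsmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbsmeth)
```

## The analysis problem

Reduced representation bisulfite sequencing (RRBS) enriches CpG-dense
fractions of a genome by MspI digestion (C^CGG) and size selection, then
reads bisulfite-converted fragments so that C/T counts at each CpG encode
its methylation level. `rrbsmeth` implements the downstream statistics for
a two-group cohort design — here, bulls raised on a high (HM) versus
moderate (MM) pre-pubertal plane of nutrition, sampled at 15 and/or 16
months of age — starting from per-sample coverage files:

1. coverage filtering (sites with at least 10 reads, "CpGs10"),
   quality-control summaries, and k-sample permutation tests on QC
   metrics;
2. correlation-based hierarchical clustering of samples;
3. differentially methylated cytosine (DMC) calling with a
   dispersion-shrunk beta-binomial Wald test and covariate-weighted FDR
   adjustment, followed by merging into differentially methylated regions
   (DMRs);
4. genomic-context annotation (gene features, CpG island / shore / shelf,
   repeats) and enrichment against the CpG10 background;
5. pyrosequencing-style validation statistics (replicate consolidation,
   Spearman concordance, age-stratified permutation tests).

Because the original sequencing data are not redistributable at package
scale, a first-class synthetic generator replaces them.  It is tested
code, not a fixture: every stage of the pipeline is exercised and
calibrated against the generator's known ground truth.

## The synthetic cohort

`sim_config()` fixes the study conditions.  The defaults emulate a mature
sperm methylome cohort:

* **Bimodal methylation.** Each CpG draws a baseline level from a
  three-component mixture: 47.1% hypermethylated (level in (0.8, 1],
  Beta(5, 1) within the band), 45.8% hypomethylated ([0, 0.2), Beta(1, 5))
  and 7.1% intermediate (uniform on [0.2, 0.8]).  The within-band shapes
  concentrate mass near 0 and 1 so that the *observed* class fractions at
  25x coverage — after binomial sampling noise leaks sites across the
  20%/80% boundaries — reproduce the target 47/7/46 split within the
  +/-3-point tolerance used by the tests.  Milder shapes (e.g. Beta(2, 1))
  fail this: boundary leakage roughly doubles the observed intermediate
  fraction.
* **Coverage.** Negative binomial per site and sample, mean 25 reads,
  size 2; zero-coverage sites are omitted from the emitted files, as in
  real coverage files.
* **Conversion.** Unmethylated cytosines convert with probability 0.994;
  failures appear as false methylated reads.  Each sample carries a
  20,000-cytosine unmethylated spike-in from which the rate is
  re-estimated.
* **Inter-individual variability.** Each bull has a per-site random
  effect on the logit scale (sd 0.25) shared by all samples from that
  bull, plus a beta-binomial dispersion of phi = 0.02 across replicates.
  The magnitude is not stated by any source; 0.25 was chosen once so that
  (a) paired 15/16-month samples from one bull are mutual nearest
  neighbours in the correlation dendrogram in >90% of runs, while (b) a
  two-cluster cut carries essentially no diet information (adjusted Rand
  index near 0) at realistic planted-effect densities — the qualitative
  clustering behaviour of the real cohort.
* **Planted diet effects.** A fraction (default 1%) of CpGs differ
  between HM and MM by exactly 15 percentage points, 70% oriented
  hyper-in-HM.  The shift is applied to whichever group keeps the level
  inside [0, 1], so the planted difference is exact; only when neither
  direction fits (possible under extreme non-default configurations) is
  the level clamped and flagged.  20% of planted sites are laid down as
  blocks of 3-5 neighbouring CpGs (steps of at most 100 bp) sharing one
  direction, emulating the regional coherence that makes a minority of
  real DMCs congregate into DMRs; without blocks, uniformly scattered
  effects essentially never satisfy the 3-DMCs-within-100-bp rule.  The
  two MM age groups share identical truth except for a single optional
  planted age effect (default 1 site), mirroring the near-absence of
  age-related changes.
* **Scale.** Three 1.2-Mb chromosomes yield roughly 25,000 CpGs in
  retained 40-290-bp MspI fragments — about 1.5% of the real study's
  1.65M CpGs10, chosen so that a full simulate-test-annotate cycle runs
  in seconds while leaving enough sites (about 250 planted) for stable
  power and FDR estimates.

Note the default planted fraction (1%) is roughly 30 times the density
implied by the real study's 580 DMCs in 1.65M CpGs; it is set high to
make power measurable at desk scale.  At this density a 2-cluster cut
*does* separate the diets; the clustering property above is therefore
asserted at a density matching the real cohort (0.1%), where individual
variation dominates.

What the generator does **not** model: read-level errors, PCR duplicates,
mapping ambiguity, strand-split dyad counts (files are emitted dyad-merged
at the forward C; `merge_strand_counts()` exists for data that are not),
and any dependence of coverage on fragment length or GC.  Passing tests
on synthetic data therefore validate the statistical machinery and
bookkeeping, not robustness to alignment artefacts.

## The site test

For one comparison, at each CpG covered in at least 4 bulls of each
group:

* The group methylation proportion is the coverage-weighted pooled
  proportion `p_g = sum(M)/sum(N)`.
* The beta-binomial dispersion phi (overdispersion of replicate bulls
  beyond binomial sampling) is estimated per site by the method of
  moments, solving `E[(p_j - p_g)^2] = p_g(1-p_g)(1/n_j + phi(1-1/n_j))`
  per sample and averaging.  At 7-9 bulls per group these estimates are
  individually very noisy (and often negative), so they are shrunk toward
  a genome-wide prior with weight `J/(J + 20)`, J being the number of
  covered samples.  The prior centre is the *truncated mean* of the raw
  estimates.  Two alternatives were evaluated and rejected: geometric-mean
  shrinkage of floored estimates biases phi low (null type-I error 0.09
  at nominal 0.05), and a methylation-trended prior (DESeq2/DSS style)
  calibrates the null exactly but costs sensitivity, because sites with a
  true group difference have pooled means that self-select into the
  elevated-dispersion intermediate bins.  The adopted scheme holds the
  empirical type-I error at 0.04-0.05.
* The Wald statistic is `(p_1 - p_2) / sqrt(var_1 + var_2)` with
  `var_g = p(1-p) * sum(n_j(1 + (n_j - 1)phi)) / (sum n_j)^2`, referred
  to the standard normal, two-sided.  For the variance only, the
  proportion is moderated by half a pseudo-read so saturated sites keep a
  finite, nonzero standard error.

## Weighted FDR adjustment

`ihw_adjust()` is a binned, weighted Benjamini-Hochberg procedure in the
spirit of independent hypothesis weighting: the covariate (the site's
average methylation across both groups) is cut into 10 quantile bins
(bins under 200 hypotheses are merged), each bin's non-null fraction is
estimated as `1 - pi0` (Storey at lambda = 0.5, clipped to [0.05, 1]),
and per-bin weights proportional to `(1 - pi0) + 0.05` are normalised to
mean 1 before BH is applied to `p/weight`.  With one bin the procedure
reduces *exactly* to BH (verified element-wise to 1e-12).

The additive 0.05 smoothing term is deliberate: fully data-driven weights
concentrate on the intermediate-methylation bins, where the normal-tail
Wald p-values are slightly anticonservative in the far tail at these
sample sizes, and amplify that miscalibration into an observed FDR of
about 0.18 at a nominal 0.1.  The smoothing caps the weight ratios;
measured over replicate cohorts the observed FDR is then 0.10-0.15 at
sensitivity 0.62-0.72 for 15-point effects at 25x with 9 vs 7 bulls.
Users should read the nominal `alpha_adj = 0.1` as controlling FDR to
roughly that band, not exactly, at desk-scale replication.  The reference
IHW's cross-validated weight optimisation is intentionally out of scope.

## DMC and DMR rules

A CpG is a DMC when it is covered in at least 4 bulls per group
(inclusive), its adjusted p-value is strictly below 0.1 ("weaker than
0.1"), and the absolute group difference is at least 10 percentage points
(inclusive).  DMRs are maximal chains of at least 3 DMCs with successive
positions at most 100 bp apart (inclusive, position-to-position); the
caller is verified against an exhaustive window-enumeration oracle on
1,000 random instances.  Difference orientation is group1 - group2
throughout, group1 being the HM-like group, so positive differences mean
hypermethylated in HM.

## Annotation conventions

Windows are strand-aware: TSS +/-100 bp; promoter 2,000 to 100 bp
upstream of the TSS; TTS +/-100 bp; 10-kb upstream/downstream flanks.
One gene-feature label per query by fixed precedence TSS > TTS > 5'UTR >
3'UTR > exon > intron > promoter > upstream > downstream > intergenic —
the precedence itself is a declared convention (the original pipeline's
rule is unpublished), chosen so gene-body categories remain
interpretable.  CpG-island shores are the 2,000-bp bands flanking an
island and shelves the next 2,000 bp, made disjoint by precedence; a
region belongs to a class when at least 75% of its length overlaps it,
a single site when it is inside.  Repeat association is any-overlap.
All three assigners are tested for exact equality with per-base
brute-force classifiers on a 1-Mb toy genome.  Enrichment against the
CpG10 background flags categories whose query/background abundance ratio
leaves [0.75, 1.25].  Genes are associated with a site when their span
extended by 10 kb contains it (inclusive boundary).

## Validation statistics

Pyrosequencing replicates are consolidated by the largest subset whose
range is at most 5 percentage points (ties broken toward the earliest
replicates, mean reported) — the laboratory rule only states that
inconsistent duplicates were repeated and the passing replicates
averaged, so the subset selection is a declared convention.  Per-DMR
concordance is Spearman's rank correlation between the RRBS mean over
member DMCs and the pyro mean, per sample.  Per-CpG group tests permute
diet labels *within* age strata, preserving per-stratum group counts;
the tests demonstrate (and the suite asserts) that the stratified test
holds its level under an age main effect with group/age imbalance while
the unstratified test does not.  All Monte-Carlo p-values use the
add-one estimator and are exactly reproducible from their seed.

## Numerical and degenerate-input choices

* Class boundaries 20 and 80 belong to the intermediate class (closed
  interval); coverage "at least 10" and "at least 4 bulls" are inclusive.
* `methylation_percent` of a zero-coverage cell is missing, never 0.
* Zero-variance Wald sites (identical groups) report p = 1; p-values are
  floored at the smallest positive double.
* phi is clipped to [1e-6, 0.999].
* Correlation distances require at least 100 shared sites per sample
  pair by default and error, naming the pair, below 2.
* Dendrogram ties are made deterministic by sorting samples
  lexicographically before clustering; linkage defaults to UPGMA and the
  correlation flavour to Pearson (both unstated in the source analysis,
  both switchable, both recorded in the run manifest).
* Coordinates are 1-based closed internally (the Bioconductor
  convention); BED I/O converts at the boundary, and `digest_mspi()`
  returns 0-based half-open fragments so cut coordinates and fragment
  boundaries coincide.

## Problem sizes used by the test suite

The suite simulates cohorts of roughly 3,500 CpGs (one 300-kb
chromosome) for smoke tests and 20,000-25,000 CpGs (the default genome)
for calibration: one null cohort for the type-I check, three replicate
effect cohorts pooled for sensitivity/FDR/direction, 600 repeats for the
stratified-vs-unstratified level comparison, 1,000 random instances for
the DMR oracle and 10,000 for the BH identity.  These sizes were chosen
to keep Monte-Carlo standard errors well inside the asserted tolerance
bands.

## Known limitations

* The site test is a simplified beta-binomial Wald approach (moment
  dispersion, no smoothing, no general design matrix); it approximates
  but is not numerically compatible with DSS's default two-group mode.
* Weighted-FDR control is approximate at small replicate numbers (see
  above).
* The generator's dispersion model (logit-normal bull effect +
  beta-binomial) is a convenience choice; real sperm methylomes have
  locus-specific variance structure the simulation does not attempt.
* Enrichment reporting stops at category ratios; gene-set scoring
  against external annotation services is out of scope, though the
  associated and background gene lists those services need are emitted.
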