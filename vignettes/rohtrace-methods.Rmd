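---
title: "ROH-based selection signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROH-based selection signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohtrace)
```

## The problem

Strong directional selection leaves extended stretches of homozygosity in
the genomes of livestock breeds.  In a highly inbred breed with a
distinctive phenotype — the motivating case is a curly-haired pig breed —
three signals can be combined to localize the selected variation:

1. **Runs of homozygosity (ROH)** per individual, from whole-genome
   sequencing (WGS) or SNP-chip genotypes;
2. **consensus ROH regions**: intervals where the ROH of all (or most)
   members of the breed overlap, refined to **breed-specific** regions by
   removing everything also homozygous in F1 crossbreeds — a crossbreed
   carries exactly one breed haplotype, so regions still homozygous in
   crossbreeds are not breed-specific autozygosity;
3. a **breed-private variant funnel**: coding variants carried only by the
   case breed and its crossbreeds, never by controls, restricted to HIGH or
   MODERATE predicted impact, then validated by genotype-frequency tables,
   two-locus co-segregation and a dominant-model consistency check.

`rohtrace` implements all three stages plus the genomic inbreeding
coefficient F_ROH, local gene-set enrichment, an imputation-accuracy
estimator, and a synthetic cohort generator with machine-readable truth so
that every stage is testable without any external download.

## The ROH scan

The caller reimplements the classic sliding-window scan
(`snp_hit_rates()` + `segments_from_flags()` = `call_roh()`):

* a **window** of `window_snps` consecutive SNPs *passes* when it contains
  at most `window_het` heterozygous and `window_missing` missing calls;
* each SNP's **hit rate** is the fraction of passing windows among the
  full windows containing it (SNPs near chromosome ends have fewer
  windows); SNPs with hit rate ≥ `hit_rate_threshold` are run-eligible;
* maximal runs of eligible SNPs are split wherever adjacent SNPs are more
  than `max_gap_kb` apart, and reported when they contain at least
  `min_snps` SNPs, span at least `min_length_kb`, and average at most
  `density_kb_per_snp` kb per SNP.  Segment endpoints are the positions of
  the first and last SNP of the run.

Two presets ship with the package:

| parameter | `wgs` | `chip` | unit |
|---|---|---|---|
| window_snps | 20 | 20 | SNPs |
| window_het | 3 | 3 | calls |
| window_missing | 5 | 5 | calls |
| min_snps | 20 | 20 | SNPs |
| min_length_kb | 2.4 | 10 | kb |
| density_kb_per_snp | 0.12 | 1000 | kb/SNP |
| max_gap_kb | 100 | 100 | kb |

Choices that the published parameter sets leave open, decided here:

* **`hit_rate_threshold` = 0.05**, the long-standing default of the tool
  family this scan descends from; it is exposed as an explicit parameter
  because results are sensitive to it.
* **Chromosome ends**: a chromosome with fewer SNPs than the window is
  evaluated as a single truncated window rather than silently skipped
  (`truncated_window = TRUE`); short scaffolds would otherwise disappear
  from the analysis.  Set `truncated_window = FALSE` for strict
  full-window behaviour.
* **Density is evaluated per final segment** (`length_kb / n_snps`), not
  per window, matching the "at least X kb with a density of 1 SNP per Y
  kb" reading of the thresholds.
* Segment-level heterozygote/missing totals are reported but not used as
  cutoffs; no such segment-level cutoff is part of the scan definition.

An important structural consequence of the density bound: with the `wgs`
preset a segment can only ever be reported where the realized SNP spacing
is at most 120 bp (`density_kb_per_snp = 0.12`).  The preset therefore
presumes a WGS-density panel (roughly one SNP per 0.1 kb, as obtained
when ~24 M SNPs tile a ~2.3 Gb autosome); applying it to sparser data
yields, correctly, nothing.

`brute_force_roh()` is a deliberately naive second implementation — every
window enumerated explicitly, runs grown one SNP at a time — kept free of
any code shared with `call_roh()`.  The test suite requires exact
agreement between the two on hundreds of randomized instances; this
oracle equivalence is the primary correctness argument for the caller.

## Consensus and breed-specific regions

`consensus_regions()` works at base-pair resolution with an interval
sweep (via IRanges coverage): a consensus region is a maximal interval in
which at least `min_support` group members have a covering ROH
(`min_support = "all"` for strict consensus; the chip workflow also
documents an 8-of-19 mode).  Base-pair resolution is strictly finer than
the kb-scale regions being reported, so no precision is lost by not
snapping to SNPs here.

`breed_specific_filter()` subtracts every base covered by ROH in at least
`max_support_excluded` excluded-group members.  The WGS rule is
`max_support_excluded = 1` (any crossbreed ROH removes the overlap), the
chip rule is 5.  Subtraction can fragment a region; fragments below
`min_fragment_bp` (default 1000 bp) are dropped to avoid 1-bp slivers.
Because the published workflow is ambiguous about whether overlapped
regions were fragmented or removed outright, both behaviours are
available (`drop_whole_region = TRUE` for whole-region removal).

**F_ROH** is the summed autosomal ROH length divided by the autosomal
genome captured by the SNP set; the default denominator in
`genome_spec()` is 2,265,395,079 bp (pig autosome captured by a WGS SNP
set).  Breed-level inbreeding is the arithmetic mean over breed members.

## Enrichment

`enrichment()` is a local replacement for web-service gene-list analysis:
one-sided Fisher exact tests on a user-supplied gene-set table.  With `k`
list genes in a set, `K` background genes in the set, list size `n`,
background size `N`:

* `fisher_p = P(X ≥ k)`, `X ~ Hypergeometric(K, N − K, n)`;
* `ease_p` is the same tail with one success removed, `P(X ≥ k − 1)`, and
  1 when `k ≤ 1` — the conservative EASE score, flagged at the
  conventional threshold 0.1.

Removing one success can only enlarge the tail, so `ease_p ≥ fisher_p`
always; the tests assert this and check `fisher_p` against direct
hypergeometric summation.  No multiple-testing correction is applied by
default (raw EASE scores are the conventional report); Benjamini–Hochberg
columns are available with `p_adjust = TRUE`.

## The candidate-variant funnel

A **carrier** holds one or two alternative alleles (genotype 1 or 2).
The default criteria — at least 3 case carriers, at least 1 crossbreed
carrier, 0 control carriers, impact HIGH or MODERATE — encode
"exclusively in the case breed and its crossbreeds, never in controls".
Decisions where the published description is silent:

* **Missing genotypes never count as carriers** and do not count against
  the control maximum; a missing control genotype can be made
  disqualifying with `control_missing_disqualifies = TRUE`.
* The presence filter is applied before the impact filter in the staged
  report (the filters commute; the set of survivors is order-invariant).
* The same presence logic applies to interval-typed (structural) variant
  records via `two_group_presence_screen()`, optionally restricted to a
  ±40 Mb window around anchor candidate SNPs; the impact filter is
  skipped there.

## Validation statistics

`genotype_frequencies()` defaults to **total-cohort denominators**
(counts over the full cohort including missing), which is how printed
validation tables are laid out; `called_only` is available.  Display
rounding is **half-up to 3 decimals** (`round_half_up()`), because
banker's rounding cannot reproduce printed table cells; raw fractions are
always retained.  `two_locus_table()` cross-tabulates 3×3 combined
genotypes per phenotype cohort with missing-at-either counted separately.
`dominance_consistency()` lists samples contradicting a fully penetrant
dominant model over a candidate-site set.  `imputation_error()` is the
exact-match discordance on the site/sample intersection of an imputed and
an assay matrix, excluding genotypes missing in either; it is symmetric
in its arguments.

## The synthetic cohort generator

`simulate_cohort()` plants the structure the analysis assumes rather than
simulating genealogies: autozygosity tracts are written directly into
case genomes (shared "consensus" tracts in every case sample, plus
per-sample tracts), crossbreeds are built as true F1s from one
transmitted case haplotype and one control haplotype, controls are
Hardy–Weinberg draws from Beta-distributed allele frequencies, private
variants and a dominant causal locus are overlaid, and missingness and
imputation-style errors are injected last.  Truth files record every
planted object; tract coordinates are also reported snapped to SNP
positions, since a SNP-based detector cannot resolve finer than that.

Defaults mirror the WGS study design at desk scale: 9 cases, 3 F1
crossbreeds, 22 controls on 2 × 20 Mb of autosome.  Two defaults deserve
explanation:

* **`mean_spacing_bp = 100`.**  The `wgs` preset's density cap
  (0.12 kb/SNP) admits segments only where SNP spacing is ≤ 120 bp, and
  the WGS panel it was designed for has ~1 SNP per 0.1 kb.  A simulator
  emulating that panel must use comparable spacing; with sparser spacing
  the preset (correctly) reports nothing.  Chip-like data are emulated
  with `mean_spacing_bp = 50000` and the `chip` preset.
* **`background_het_rate = 0.5`.**  Outside autozygous tracts, case
  genotypes are heterozygous with probability 0.5 — maximally informative
  segregating sites.  This is a deliberate idealization: the
  window/threshold scan is permissive, and at realistic informativeness
  (het rates of 0.25–0.35 at segregating sites) it flags an appreciable
  fraction of a purely outbred genome as short ROH — which is consistent
  with the substantial baseline inbreeding estimates such scans report
  even for outbred breeds.  With background heterozygosity at 0.5 the
  background contribution is negligible (the suite checks that a
  tract-free simulation yields under 1% background ROH coverage), so
  planted-truth recovery can be scored cleanly.  Consequently, passing
  recovery tests demonstrate correctness of the detector on well-separated
  signal, not the (method-inherent) false-positive behaviour on weakly
  informative real data.

What the generator does **not** emulate: linkage disequilibrium,
recombination maps, mutation models, allele-frequency ascertainment, and
pedigree structure beyond a single F1 cross.  Tests passing on this
generator therefore say nothing about LD-induced artifacts in real data.

## Numerical conventions and degenerate inputs

* All internal coordinates are **1-based, fully closed** (VCF
  convention); conversion to 0-based half-open happens only in the BED
  writer, and `read_bed()` restores 1-based intervals exactly.
* Missing genotypes are `NA` internally; VCF `./.` and PED `0 0` map to
  `NA` on input and back on output.
* PED recoding is against the observed major allele, ties broken
  alphabetically; a monomorphic site keeps the placeholder minor allele
  `"0"`.
* Multi-allelic VCF records are split into biallelic records sharing the
  position by default (configurable to skip); the site table allows equal
  positions only for distinct alternative alleles.  Impact is the highest
  severity across ANN transcript entries.
* The two documented site-depth conventions (mean depth ≥ 6 for the ROH
  dataset, ≥ 10 for the variant funnel) are both available through
  `depth_qc_params(min_mean_dp = ...)`.
* Empty inputs return empty, correctly-typed results wherever a
  continuation is meaningful (no segments, no consensus, empty funnel);
  contract violations — overlapping per-sample segments in `froh()`,
  unknown samples, unsorted VCFs, identical loci in
  `two_locus_table()` — are hard errors.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
the study-scale simulation uses 2 × 20 Mb at 100 bp spacing (~400,000
sites × 34 samples), oracle-equivalence checks use hundreds of randomized
instances of up to 200 SNPs with fully randomized parameters, and
property checks (consensus per-base oracles, enrichment inequalities,
binomial recovery of injected error rates) use dimensions chosen so the
whole suite completes in about a minute.

## Known limitations

* The scan reproduces the sliding-window algorithm as specified, including
  its permissiveness at low marker informativeness; it is not an
  HMM/likelihood ROH caller and no LD pruning is applied.
* Enrichment treats gene sets as flat lists; no ontology propagation.
* Sex-chromosome ROH, phased genotypes, and binary PLINK/BCF inputs are
  out of scope.
* The chip workflow's consensus support modes are implemented, but chip
  presets are exercised at desk scale only.
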