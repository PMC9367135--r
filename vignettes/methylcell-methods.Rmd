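---
title: "Calling cell-type differential methylation with methylcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling cell-type differential methylation with methylcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylcell)
```

## The analysis problem

Sorted immune cell populations share a genome but not an epigenome. Whole
genome bisulfite sequencing (WGBS) reads out CpG methylation as per-site
counts of methylated and unmethylated observations, and regions whose
methylation rate depends on cell type — cell differentially methylated
regions, cDMRs — are candidate regulatory elements. Within a cDMR, the
cell type(s) in which methylation is specifically *low* (cell lowly
methylated regions, cLMRs) are of particular interest because
hypomethylation at promoters and enhancers is generally permissive to
transcription-factor binding and transcription.

`methylcell` implements this analysis as a reusable pipeline for a
cell-by-animal design: nine sorted porcine immune populations (`CD4T`,
`SWC6gdT`, `Myeloid`, `CD8T`, `Neut`, `CD21nB`, `CD21pB`, `NK`,
`CD4CD8T`) from two animals, one WGBS library per cell x animal. Every
stage also runs on synthetic data with known ground truth, which is how
the package tests itself.

## Regional methylation: tiling and filtering

CpG reports (Bismark cytosine-report dialect) are read per sample, the
two strands of each CpG merged, and counts pooled into fixed 1 kb tiles
anchored at coordinate 0. A tile's methylation rate in a sample is the
pooled ratio `sum(n_meth) / sum(n_total)` over its CpGs — the
coverage-weighted convention, not the mean of per-CpG rates, so deep CpGs
weigh more and shallow ones add little noise.

The coverage filter retains a tile only if, for **every** animal, more
than `min_coverage = 25` pooled reads are present in at least
`min_cell_types = 7` of the 9 cell types (strict inequality). "Coverage"
here means the pooled read count over the tile's CpGs; a mean-per-CpG
alternative is available via `coverage = "mean_cpg"` since the regional
convention is a genuine modelling choice.

## The cell-effect test

Per retained tile the model is additive in cell type and animal,

```
rate_ij = mu + cell_i + animal_j + e_ij
```

fitted by least squares; the cell effect is tested with the extra sum of
squares F statistic comparing the full model against the animal-only
reduced model. With one observation per cell x animal a random animal
intercept is not separable from its fixed-effect counterpart — the
animal variance and residual variance cannot be distinguished — so the
animal term enters as a fixed effect and the resulting F is exactly the
classical balanced two-way ANOVA F on complete designs (the package
tests this equivalence against the direct sum-of-squares formulas, and
against a hand-worked 3 cells x 2 animals example where `F(2,2) = 28`
and `p = 1/29`). Missing cells are allowed; tiles whose residual degrees
of freedom vanish are flagged untestable and excluded from the
multiple-testing batch.

Benjamini–Hochberg correction is applied once genome-wide (a single FDR
batch, not per chromosome), and tiles with `q < 0.01` are cDMRs.

Numerical edge cases are handled explicitly: a constant response gives
`F = 0, p = 1`; an exact fit (zero residual sum of squares) is flagged
and its p-value floored at `1e-300` so BH stays well defined.

## cLMR classification

For each cDMR, each sample's rate is standardized by the mean and the
sample (n-1) standard deviation across all of that region's samples; a
cell's average z-score is the mean of its samples' z-scores. A (region,
cell) pair is a cLMR when the average z-score is below -1 **and** the
cell's mean methylation rate is below 75% (and the region is a cDMR).
Whether the z-scores should be taken over the 18 sample rates or over
the 9 cell-type means is genuinely ambiguous; sample-level is the
default and `z_level = "cell"` provides the alternative. The 75% bound
is evaluated on the cell mean, not on each replicate.

## Annotation conventions

Windows are deliberately explicit because each is a choice, not a fact:

* promoter: the strand-aware 2 kb window upstream of the TSS through the
  TSS (a symmetric window is not used; `promoter_bp` is configurable);
* TTS: 1 kb either side of the termination site;
* CGI shore: 2 kb flank of a CpG island;
* precedence promoter > TTS > exon > intron > intergenic, and
  CGI > shore > non-CGI; any 1 bp overlap qualifies.

Interval arithmetic goes through `GenomicRanges` (1-based closed, the
Bioconductor convention); region tables and BED output use 0-based
half-open starts as BED requires, and CpG/SNP positions stay 1-based as
in their source formats.

Intergenic regions are assigned the gene with the nearest TSS under the
stated gap convention: distance 0 when the TSS lies inside the region,
otherwise `start - tss + 1` (TSS upstream of the region start) or
`tss - end + 1` (TSS at or beyond the exclusive end), both in 0-based
coordinates; ties resolve to the lexicographically smallest gene id.

Feature enrichment of per-cell cLMR sets uses tiles as sampling units
(tiles are the analysis unit throughout): an upper-tail hypergeometric
test with the retained tiles as universe.

## Methylation–expression integration

Correlations are Pearson, computed over the nine per-cell means (the
expression data have only 1–2 replicates per cell, so cell means are the
stable unit; per-sample pairing is not attempted). TPM is
`log2(TPM + 1)`-transformed by default to stabilize the correlation on
skewed abundances; the transform can be switched off. Pairs with fewer
than three cells or a constant vector are excluded. cDMR correlation
distributions are compared per feature stratum (promoter, intragenic,
TTS, intergenic) against an equal-size seeded random draw of non-cDMR
tiles of the same stratum, with a one-sided Wilcoxon rank-sum test for a
left shift (exact below 25 observations per group, normal approximation
with continuity correction above). The background draw excludes cDMR
tiles — whether the original analysis did is unstated, but a background
contaminated with signal would only make the test conservative.

Region–expression pairs are then classed as significantly positive or
negative at a nominal `p < 0.05` (no threshold is inherited from
anywhere; it is configurable) and a one-sided Fisher's exact test per
stratum and sign asks whether cDMRs are enriched for signed
correlations relative to the background. Gene-set overlap between
cLMR-carrying genes and expression-enriched genes (log2FC > 1,
FDR < 0.05 per cell type), and GWAS SNP overlap per trait class, both
use upper-tail hypergeometric tests; the SNP universe is every SNP in
the supplied table.

## Motif enrichment

The motif stage is a deliberately simplified, deterministic counterpart
of reference motif-enrichment tools. Sequences are scored with the
average odds score: for every window of PWM width on both strands, the
odds `prod(pwm[j, base] / background[base])`, averaged over all scored
windows. The background is 0-order uniform 0.25 by default. Zero PWM
probabilities are floored at `1e-4` before forming odds (set
`zero_floor = 0` to score exact zeros, which the toy examples use).
The threshold for calling a sequence positive for a motif is the 95th
percentile of the control scores — fixed rather than optimized, so the
one-sided Fisher's exact test on (positive/control) x (above/at-or-
below) stays valid. Scores are computed with a palindromic pairwise
accumulation so that strand symmetry,
`score(seq) == score(revcomp(seq))`, holds bit-exactly in floating
point, not just approximately. Results are method-parallel to reference
tools, not numerically comparable to them.

## The synthetic study

`sim_config()` + `simulate_study()` emulate every pipeline input:

* 9 cell types x 2 animals, one report per sample;
* CpG sites placed with exponential spacing (mean 100 bp, roughly the
  genome-wide CpG density of the pig genome), 10x denser inside CGIs so
  the observed/expected CpG ratio inside islands exceeds 0.6;
* per-tile baseline rates `Beta(8, 2)` (mean 0.8, matching the 80–84%
  global methylation typical of mammalian immune cells);
* planted cDMRs depress one cell type's rate by `dmr_effect` (default
  0.3); planted baselines are drawn truncated so the depressed rate
  stays in [0, 1];
* a per-animal offset on the logit of the rate (`animal_effect_sd`,
  default 0.1) keeps rates in (0, 1) while honouring the additive
  animal term;
* per-CpG depth `Poisson(mean_depth = 30)` and methylated counts
  binomial — an overdispersion-free stand-in (the real data's depth
  distribution is unknown), adequate for testing filters and tests but
  not a claim about WGBS noise;
* expression: linked genes (a `frac_genes_correlated` fraction, linked
  through their promoter tile, which becomes an additional planted
  cDMR) get `log2 TPM` as a monotone function of the linked region's
  true methylation (slope 10 log2-units per unit rate, so a 0.3
  depression yields a > 1 log2FC enrichment in the hypomethylated
  cell), plus lognormal noise; the enriched-gene table is derived from
  the true cell-level fold changes;
* SNPs per trait class, with a configurable fraction of the immune
  class planted inside cDMR tiles; a planted consensus PWM (probability
  1 columns) among random decoys, embedded in 60% of positive-tile
  sequences.

The same seed reproduces every output byte-identically
(`simulate_expression` and `simulate_annotation_and_snps` derive their
streams from `seed + 1` and `seed + 2`).

What the generator does **not** emulate: read-level artefacts
(alignment bias, incomplete conversion, duplicates), overdispersed
depth, spatial correlation of methylation along the genome beyond the
tile unit, isoform structure, and realistic motif composition of real
promoters. Passing tests therefore demonstrate correctness of the
statistics and plumbing under the stated model, not robustness to every
property of real WGBS data.

## Problem sizes and calibration checks

The test suite runs the whole pipeline at desk scale: null calibration
on a 2,000-tile genome (KS test of the cell-effect p-values against
Uniform(0, 1), and no more than 2 spurious cDMRs at FDR < 0.01); signal
recovery on a 5,000-tile genome with 200 planted cDMRs at effect 0.3
and depth 30 (sensitivity >= 0.9, empirical FDR <= 0.05, and >= 95%
correct-cell cLMR attribution among called regions); integration
recovery with 30% of genes negatively linked (promoter-stratum Wilcoxon
and Fisher p < 0.01); motif recovery with the planted motif ranked
first among 10 decoys at p < 1e-6. All hypergeometric, Fisher and
Wilcoxon p-values are verified against exhaustive enumeration on
universes up to 12 at 1e-12. `scripts/acceptance.R` re-runs these
analyses from scratch at a caller-chosen seed.

## Known limitations

* The fixed-effects ANOVA is exact for the balanced 2-animal design it
  targets; with many animals per cell a genuine mixed model would gain
  power and the package does not provide one.
* No beta-binomial dispersion modelling or smoothing across tiles:
  tiles are independent units, as in the regional-rate convention it
  follows.
* One TSS/TTS per gene model; multi-isoform promoters are not
  represented.
* The motif stage's p-values depend on the fixed control-quantile
  threshold; they order motifs well but are not calibrated against
  reference tools.
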