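---
title: "Detecting cis-regulatory divergence by allele-specific expression in F1 hybrid crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cis-regulatory divergence by allele-specific expression in F1 hybrid crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossASE)
```

## The experimental design this package models

Two partially inbred *Anopheles gambiae* colonies with different
insecticide-resistance phenotypes are reciprocally crossed. Pools of F1
females are RNA-sequenced; the mothers, candidate fathers and individual
male siblings are genome-sequenced. In an F1, both parental alleles share
one *trans* environment, so allelic read-count imbalance at heterozygous
exonic SNPs isolates *cis*-regulatory divergence between the colonies.

Three genotype-driven complications shape the pipeline:

* **Paternity is uncertain.** Males are sequenced as a pool of candidates;
  each cross's father is assigned by minimising the median per-progeny
  Mendelian error rate (`match_father()`). A triple is an error when no
  gamete pair from the putative parents can produce the child genotype;
  missing calls are uninformative and excluded from both numerator and
  denominator (unbiased under missingness at random).
* **Some mothers fail sequencing.** For those crosses, informative SNPs
  are inferred from the male siblings (`infer_sibling_snps()`): a site
  where the parents were homozygous for different alleles makes every
  sibling heterozygous. The inferred sites are phase-unknown, so those
  crosses are analysed in unphased mode. The screen leaks sites where a
  het × het or hom × het parent pair produced an all-het sibship by
  chance, at rate (1/2)^(number of called siblings) per such site; with
  six siblings this is a ~1–2% contamination, quantified in the tests.
* **Sample swaps happen.** Scoring a cross's RNA with the wrong parents'
  SNP set inflates apparent imbalance, because many of those sites are not
  heterozygous in the mis-matched F1. `mismatch_diagnostic()` summarises
  mean |fraction − 0.5|; the synthetic swap experiment
  (`simulate_swapped_counts()`) reproduces the inflation.

## The gene-level ASE test

SNP-level counts are filtered at ≥ 10 total reads, then aggregated per
gene. Without phase, the higher-count allele at each SNP is assigned to a
putative major haplotype ("pseudo-phasing") and the gene's major allele
frequency (MAF) is the summed major counts over summed totals — a
statistic that is ≥ 0.5 by construction and upward-biased at low coverage,
which is why its null distribution is obtained by simulation rather than
from a closed form: `gene_ase_test()` redraws each SNP's count from a
beta-binomial with mean half the (fixed) total and overdispersion
ρ = 0.038, re-aggregates each replicate identically (pseudo-phasing
replicates in unphased mode; fixed haplotype assignment in phased mode),
and reports the proportion of replicates whose MAF reaches the observed
one. The default replicate count is 10⁶; the analysis scripts and tests
use 10⁴, which resolves p-values to 10⁻⁴ — ample for a 5% FDR decision on
cohorts of ~10³ genes.

The p-value is deliberately the raw proportion, so it can be exactly 0 at
finite replicates; an optional (k+1)/(n+1) estimator exists
(`add_one = TRUE`) but is off by default. Monte-Carlo accuracy is tested
against the exact beta-binomial tail for single-SNP genes, where the null
distribution has a closed form.

**Heterogeneity.** For multi-SNP genes the same replicates yield a
heterogeneity p-value from the count-weighted dispersion of per-SNP
major-haplotype fractions, Q = Σᵢ nᵢ (fᵢ − f̄)², with f̄ the count-weighted
mean. Q is invariant to which haplotype is labelled major. This
construction is this package's own; it is one operation
(`heterogeneity part of gene_ase_test()`) and can be swapped out without
touching the rest of the pipeline. A small p_het means the SNPs of a gene
disagree about the direction/extent of imbalance — isoform-specific ASE or
annotation problems — and is reported, not filtered on.

**Overdispersion.** ρ is the intraclass correlation of a beta-binomial
with α = μ(1/ρ − 1), β = (1 − μ)(1/ρ − 1); at μ = ½ and ρ = 0.038,
α = β ≈ 12.66, and the model collapses to the binomial as ρ → 0.
`estimate_overdispersion()` fits ρ by bounded one-dimensional maximum
likelihood with μ fixed at ½ and compares against the binomial by a
likelihood-ratio test on the 0.5·χ²₀ + 0.5·χ²₁ boundary mixture. Because
μ is fixed, genuinely imbalanced genes inflate the estimate — visible when
naively pooling a cohort with 20% cis-regulated genes — so the estimator
should be read as an upper bound unless run on balanced data; the null
model's ρ stays at the study value 0.038 regardless.

**Gene-to-SNP mapping.** Genes are the analysis unit via annotation
overlap; a SNP inside two overlapping genes contributes to both. Per-gene
null streams are derived deterministically from the global seed and the
gene id, so results are identical whatever the input row order; SNPs are
ordered by position within a gene before simulation for the same reason.

## Combining crosses

Each cross yields a detectable set (genes with informative SNPs passing
the depth filter) and a significant set (BH q ≤ 0.05).
`intersect_ase()` tabulates exclusive (UpSet-style) intersection counts.
`permute_intersection()` tests the all-cross overlap: each permutation
draws, per cross, a uniform subset of the shared detectable universe of
the same size as that cross's significant set, and records the all-cross
overlap. The expectation under independence is N·Π(kᵢ/N). Draw sizes are
restricted to the universe by default; the full-set mode exists because
the published description is ambiguous on this point, and the chosen mode
is recorded in the output. Here — unlike the ASE p-value — the add-one
estimator (1 + #{null ≥ obs})/(n_perm + 1) is used, because a reported
permutation p of exactly 0 is never defensible; the asymmetry with the
ASE p-value definition is intentional.

The consistency list (`consistency_table()`, default: significant in ≥ 4
of 6 crosses) is the unit for downstream enrichment, with direction
tallies contributed only by phased crosses.

## Enrichment and confounders

* **Copy-number variants** can mimic ASE: if the two SNP-bearing copies of
  a duplicated gene split 2:1 between haplotypes, the expected allelic
  fraction is 2/3 without any cis-regulatory change. `cnv_flag()` marks
  genes with any individual at copy number ≠ 2, and the ASE/CNV 2×2 table
  is tested by a two-sided Fisher exact test reporting the *sample*
  (cross-product) odds ratio — the published values match it at one
  decimal; the conditional-MLE odds ratio is not computed. The test is
  restricted to autosomal genes, and "non-ASE" genes are those detectable
  in every cross but significant in none.
* **Selective sweeps**: a gene is "swept" if its interval overlaps any
  swept interval by ≥ 1 bp; same 2×2 machinery.
* **Gene ages** come from Wagner parsimony on a binary presence/absence
  matrix over a rooted species tree: a Sankoff up/down dynamic programme
  gives, for every node, the minimum tree-wide change count conditional on
  that node's state; the age class is the root-most ancestor of the focal
  tip that is present in at least one minimum-change labelling, i.e. ties
  resolve toward the older origin. One consequence: a gene absent only in
  the root's other child cannot be distinguished from a root-origin gene,
  so the generator never plants that class.
* **Chromosome arms**: a two-way main-effects ANOVA of per-(arm, cross)
  ASE proportions, computed from marginal means on the complete balanced
  grid (residual df = (A−1)(C−1)), on raw proportions (the published
  analysis does not state a transformation; raw is the simplest defensible
  choice). Note the per-cross cells are not independent when the same
  genes drive ASE in every cross, so the arm effect captures any
  consistent arm-level clustering of ASE genes, not only a causal arm
  effect.
* **CRM assignment**: each predicted cis-regulatory interval maps to all
  genes it overlaps plus the nearest non-overlapping gene on each side
  (both neighbours for an intergenic CRM); equidistant ties are all
  reported.

## The synthetic cohort generator

`simulate_cohort()` produces everything the pipeline consumes, with known
truth. What it emulates, and the defaults chosen once as study
conditions:

| aspect | default | rationale |
|---|---|---|
| crosses / siblings | 6 crosses, 6 male sibs, 2 crosses unphased | the experimental design |
| SNP sites per gene | Poisson(25) candidates | yields a handful of informative sites per gene per cross, matching the ~10⁵ usable exonic SNPs over ~1.4·10⁴ genes |
| colony structure | 8% of sites fixed differences; 90% of the rest segregating at frequency 0.5 in both colonies | per-cross informative sets far exceed the colony consensus differences, as observed |
| coverage | negative binomial, mean 100, size 10 | desk-scale stand-in; no per-gene coverage distribution is published |
| allelic noise | beta-binomial, ρ = 0.038 | the study's overdispersion |
| cis-regulation | 20% of genes, true MAF 0.7, random direction | strong enough to measure sensitivity, weak enough not to trivialise it |
| CNV confounding | 10% of genes, one parent at 3 copies; F1 fraction copy-weighted (2:1 ⇒ 2/3) | gives the CNV-vs-ASE test a realistic positive signal |
| gene ages | 8-tip ladder tree, focal tip `t1`; presence = the origin clade | parsimony recovers the planted class exactly |
| missingness | 2% per call | exercises the uninformative-site paths |

The generator does **not** model read-level artefacts (mapping bias,
duplicates), linkage disequilibrium, unexpressed genes, X hemizygosity in
males, or isoform structure. Consequently a passing test suite shows the
statistics behave correctly under the stated noise model — it does not
certify robustness to alignment bias, which in real data is handled
upstream of the counts this package ingests.

Determinism: one global seed fans out into named substreams
(layout/parents/truth/per-cross counts/…), so identical configurations
give byte-identical bundles and stages can be re-run independently.

## Numerical and edge-case choices

* Ties `count_a = count_b` contribute 0.5 to MAF (unbiased under the
  null) rather than being dropped.
* Zero-total SNPs must be filtered before testing; the depth filter
  guarantees this in the pipeline.
* MAF comparisons in the Monte-Carlo tail use a 10⁻¹² slack so that exact
  ties (identical rational numbers) count as ≥, immune to floating-point
  representation.
* `fisher.test` can return p = 1 + ε by accumulation; values are clamped
  to 1.
* Father matching with zero informative sites excludes the candidate with
  a warning; the median over progeny uses the mid-mean for even counts.
  The default `max_error` = 0.05 is configurable: with strongly inbred,
  weakly diverged colonies, same-colony non-fathers can sit near the true
  father's error rate, and the threshold expresses how conservative a
  "good match" must be.
* The arm ANOVA errors on incomplete grids instead of silently dropping
  cells; with a zero residual it reports F = 0, p = 1 (flat table) or
  F = ∞, p = 0.

## Problem sizes

The shipped analyses and tests use cohorts of 150–1200 genes, 10³–10⁴
null replicates per gene and 10⁴ permutations — sizes chosen so the whole
workflow re-runs in minutes on a laptop while keeping every Monte-Carlo
tolerance (3 standard errors) meaningful. The study-scale configuration
(10⁶ replicates, 10⁵ permutations) is the package default for real use.

## Known limitations

* p_het's construction is this package's own; results for multi-SNP genes
  with strong isoform effects are not comparable to other tools'
  heterogeneity flags.
* The overdispersion MLE assumes balance (μ = ½); run it on null-like
  data or treat it as an upper bound.
* Unphased mode cannot call direction, and its pseudo-phased MAF is not
  comparable in power to phased mode at a given coverage.
* With heavy inbreeding and low colony divergence, Mendelian-error
  paternity assignment distinguishes same-colony candidates only weakly.
* The permutation universe (detectable in *all* crosses) is conservative
  when detectability varies strongly between crosses.
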