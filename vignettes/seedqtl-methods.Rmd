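---
title: "Models and methods behind seedqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seedqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedqtl)
```

seedqtl implements the computational core of a qualitative-trait mapping
study in an F2 intercross: Mendelian and epistatic segregation analysis,
the QTL-seq bulked-segregant scan, marker–phenotype association tables,
and light two-point linkage utilities, together with a synthetic-data
generator that stands in for raw sequencing so the whole pipeline can be
exercised and validated at desk scale. The motivating system is
watermelon seed-coat color, governed by the classical four-gene model
(`R`, `T`, `W` and the modifier `D`), but every component is generic over
penetrance models and marker designs.

## Penetrance models and expected ratios

A *penetrance model* maps multi-locus genotype classes to phenotype
labels. Genotypes at a locus are summarized by the dominant-allele count
(2, 1, 0), so `k` loci define `3^k` concrete classes. Rules are written
in the classical shorthand (`R_` for a dominant carrier, `rr` for the
recessive homozygote, `__` for "any") and are evaluated **first match
wins**. This is deliberately how epistasis is expressed: a rule
`"R_ __" -> dotted black` placed first encodes that a dominant `R`
allele masks the second locus entirely, without having to enumerate the
masked classes.

Expected F2 ratios come from enumeration: each locus contributes
genotype weights 1:2:1 (out of 4), weights multiply across loci under
independent assortment, and the per-phenotype sums are reduced by their
greatest common divisor. Dominant epistasis yields 12:3:1, recessive
epistasis 9:3:4, no interaction 9:3:3:1, and `classify_epistasis()`
labels a locus pair by matching against these canonical patterns.
Linkage between loci is ignored here on purpose — the ratio tests in the
source populations assume independent assortment, and linkage is the
simulator's job.

The packaged four-gene model (`seed_coat_model()`) reproduces the
published phenotype classes: flat black (`R_T_W_D_`), dotted black
(`R_T_W_dd`), green (`rrT_W_`), tan (`R_ttW_`), clump (`R_T_ww`), red
(`rrttW_`), white tan-tip (`R_ttww`) and white pink-tip. The classical
description leaves the `rr T_ ww` class unnamed; this package folds all
`rr · ww` classes into "white pink-tip" so the 81 concrete classes are
fully partitioned. The choice affects no two-locus ratio used anywhere
in the package (those fix the other loci in the dominant state), it only
guarantees that classification is total. The `T1` locus name records
that the tan1/red-segregating locus may be an allele of `T` or a
distinct gene; the model treats locus identity purely as a label.

```{r ratios}
m <- seed_coat_model()
expected_phenotype_ratio(m, "R")
expected_phenotype_ratio(m, c("W", "D"), fixed = c(R = "RR", T1 = "TT"))
```

## Segregation tests

`chi_square_gof()` is the uncorrected Pearson goodness-of-fit statistic
with expected counts proportional to the hypothesized ratio and
`classes - 1` degrees of freedom; no Yates correction is applied because
the classical segregation statistics are computed without it. A note is
emitted when an expected count falls below 5 (F2 recessive classes are
routinely this small — e.g. an expected count of 6 in a 96-plant
12:3:1 population — so the condition is reported, not fatal).
`select_ratio()` tests a set of candidate ratios and ranks them by
p-value; `distortion_test()` specializes the test to 1:2:1 marker
segregation and drives the QC filter (default alpha 0.0001, the
conventional mapping cut-off).

## The synthetic F2 generator

The generator emulates the study designs (populations of 96–178
individuals, phenotype-selected bulks of 18/18 or 20/7, whole-genome
bulk sequencing at about 83x):

* **Recombination.** Gametes are Markov chains along each chromosome:
  inter-marker recombination fractions come from inverting the chosen
  map function (Kosambi by default) on the inter-marker distance in cM.
  Physical distance converts to genetic distance at a fixed
  `bp_per_cM`, 300 kb/cM by default — the scale of a compact ~365 Mb
  plant genome spanning roughly 1200 cM. There is no interference
  beyond what the map function implies, which is standard and
  sufficient for validation at this scale.
* **Allele orientation.** The alternate allele at every marker is
  defined as the recessive-phenotype parent's allele. The recessive
  bulk's SNP-index therefore rises toward 1 over a causal locus and the
  recessive-minus-dominant delta is predictably positive, matching the
  direction conventions of the source analysis.
* **Sequencing.** Per position and bulk, total depth is Poisson around
  the mean (83 by default; the source reports only an average, not a
  depth distribution) and alternate reads are binomial with success
  probability `q(1-e) + (1-q)e`, where `q` is the true allele frequency
  among the bulk's 2m chromosomes and `e` a per-read error rate
  (default 0.005; the source states none, so it is configurable and
  small).

Two analytic anchors follow from the genetics alone and are used
throughout the tests: a bulk of recessive segregants has `q = 1` at the
causal locus, while a bulk of dominant-phenotype carriers has
`q = 1/3` (carriers are 1 AA : 2 AB), so the recessive-minus-dominant
delta SNP-index tends to `2/3` as depth and bulk size grow.

What the generator does **not** emulate: read-level artifacts (mapping
bias, duplicated reads, base-quality structure), variant-calling error,
segregation distortion, or non-random bulk membership (the real bulks
were chosen from available phenotyped plants). Passing simulation tests
therefore validates the statistical machinery under clean Mendelian
sampling, not robustness to alignment pathology.

## The QTL-seq scan

The per-site SNP-index of a bulk is `alt / (ref + alt)`; the delta
SNP-index is the difference between the two bulks in a declared order
(the order is required, since the sign identifies which parent
contributes the high-index allele). Site filters follow the originating
QTL-seq method's conventions, as the source describes its filtering
only as a custom script: minimum total depth 10 in each bulk, and
removal of sites with SNP-index below 0.3 in *both* bulks
(uninformative sites where the variant is essentially absent from both
pools). All filter values are configurable and a per-category filter
report is attached to the track.

Windows of 1 Mb advance in 10 kb steps from position 1 of each
chromosome (1-based, half-open `[start, start + window)`, the VCF
position convention, which keeps the tiling arithmetic exact). A window
must hold at least 10 sites to participate in calling — an unstated
detail in the source, chosen to prevent single-SNP artifacts; truncated
end-of-chromosome windows are retained under the same site rule.

Significance comes from a no-QTL simulation that accounts for
population size, bulk sizes and read depth: each replicate draws an F2
population at an unlinked 1:2:1 locus, samples both bulks without
replacement, and adds binomial read noise at the simulated depth. Read
counts make this null distribution discrete (delta atoms at multiples
of `1/depth`), so the calling threshold is the smallest observed
`|delta|` whose empirical upper-tail probability is at most alpha, and
a window is significant when its `|mean delta|` *reaches* that value —
the standard critical-value convention for discrete statistics. A
plain quantile with strict exceedance would be systematically
conservative at these depths. A tie tolerance of 1e-9 absorbs
floating-point representation differences between equal atoms.
Thresholds are simulated on a depth grid and linearly interpolated at
the window's mean site depth (the source states depth-aware thresholds
but not the window-level aggregation rule; the mean-depth lookup is
this package's choice, with the grid and replicate count exposed as
configuration). No correction beyond these simulated bands is applied,
mirroring the fixed p < 0.05 / p < 0.01 band approach; under a no-QTL
simulation the per-window call rate at alpha behaves accordingly and is
documented by the calibration tests rather than adjusted.

Consecutive significant windows merge into maximal intervals; the peak
is the window with the largest `|mean delta|`, and the signed peak
statistic is reported.

## Marker association and linkage utilities

Association tables cross-tabulate marker genotype classes (carrier
classes pool the dominant homozygote with the heterozygote) against
phenotypes, with missing calls excluded from every denominator.
Percentages are reported both at full precision and truncated — not
rounded — to two decimals, because that is how the validation
accuracies were printed (65/71 appears as 91.54, 7/9 as 77.77). The
two-marker table applies an ordered first-match rule, the natural form
of an epistatic prediction ("any `R` carrier is dotted black regardless
of the second marker"). `accuracy_vs_recombination()` is deliberately
descriptive: it pairs the misprediction percentage with the summed
marker–locus cM distances and performs no test.

Phenotype-to-marker encoding uses the JoinMap-style `a/h/b/c/d` codes:
a phenotype class maps to the set of locus genotypes compatible with it
under the penetrance model, and the set determines the code (`c` =
not-a, `d` = not-b). Classes in which a locus is epistatically masked
(all three genotypes possible) become missing — clump-seeded
individuals, for instance, carry no information about the `D` locus.

Two-point recombination fractions are maximum-likelihood estimates for
an F2 in coupling phase, marginalizing dominant codes over their
compatible genotype cells, so codominant and dominant codings mix
freely. The likelihood is scanned on a dense grid (step 1e-4) and
refined locally with `optimize()`; the grid-first strategy is
derivative-free and robust for the dominant-by-dominant case, whose
likelihood is nearly flat toward 0.5. Estimates are capped at 0.499
before the Kosambi conversion (`d = 25 ln((1+2r)/(1-2r))`) so unlinked
pairs keep finite distances. Full multipoint ordering and grouping are
out of scope: the published map positions (e.g. a locus at 14.5 cM or a
1,226 cM total map) depend on the complete genotyping-by-sequencing
dataset and the mapping software's ordering algorithm. The desk-scale
property standing in for them is additivity — adjacent two-point
Kosambi distances on a simulated chromosome sum to its map length — and
that is what the test suite checks.

## Problem sizes and reproducibility

The validation suite runs the study designs at their real sizes
(population 128 with 18/18 bulks, depth 80–500) with 10,000 null
replicates for thresholds, 100 seeds for QTL recovery, 200–300
replicates for the analytic-limit and rf-recovery checks; these sizes
keep every Monte-Carlo standard error a few times smaller than the
tolerance being asserted. Every stochastic function accepts an explicit
seed and is bit-reproducible under it; `scripts/acceptance.R` derives
all sub-seeds from a single `--seed` argument.

## Known limitations

* Penetrance is deterministic; incomplete penetrance and phenotyping
  error are not modeled.
* The scan starts from allele depths; alignment and variant calling are
  upstream of the package by design.
* Null thresholds assume a biallelic 1:2:1 locus and unlinked sites;
  the windowed statistic averages linked sites, so the per-window
  threshold is design-calibrated per site, not family-corrected.
* The Kosambi/Haldane inversion of physical distance assumes a uniform
  `bp_per_cM`; real recombination landscapes are not uniform.
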