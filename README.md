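# seedqtl

Qualitative-trait mapping in F2 intercross populations, built around the
genetics of watermelon seed-coat color. Seed-coat color in watermelon is
classically explained by four genes — `R`, `T`, `W` and a modifier `D` —
whose dominance and epistasis relations produce phenotypes such as flat
black (`R_T_W_D_`), dotted black (`R_T_W_dd`), green (`rrT_W_`), tan,
clump and red. seedqtl provides, for this and any comparable qualitative
trait:

* **Penetrance models with epistasis** — ordered genotype-class rules
  (`"R_ __" → dotted black`), expected F2 ratio enumeration over the
  `3^k` genotype classes, and classification of two-locus interaction as
  none (9:3:3:1), dominant (12:3:1) or recessive (9:3:4) epistasis.
* **Segregation tests** — the Pearson goodness-of-fit statistic
  `χ² = Σ (O−E)²/E` against Mendelian ratios, ratio-hypothesis ranking,
  and a 1:2:1 segregation-distortion QC filter.
* **The QTL-seq scan** — per-site SNP-index (`alt / (ref+alt)` per
  bulk), delta SNP-index between two phenotype-selected bulks, 1 Mb /
  10 kb sliding windows, simulation-based significance thresholds that
  account for population size, bulk sizes and read depth, and QTL
  interval calling with BED export.
* **Marker–phenotype association** — single- and two-marker prediction
  accuracy tables with the field's truncated-percentage reporting, and
  the misprediction-vs-recombination comparison.
* **Linkage utilities** — JoinMap-style `a/h/b/c/d` phenotype encoding
  with epistatic masking, two-point maximum-likelihood recombination
  fractions for codominant and dominant codings, and the Kosambi map
  function `d = 25·ln((1+2r)/(1−2r))`.
* **A synthetic F2 generator** — Markovian recombination along a
  genetic map, phenotype assignment under a penetrance model, phenotype
  bulk selection, and Poisson/binomial bulk read-depth sampling — so the
  entire pipeline runs and validates itself at desk scale.

See `vignettes/seedqtl-methods.Rmd` for the models, defaults and design
choices in detail.

## Worked example

```r
library(seedqtl)

## Does a 67:22:7 phenotype segregation fit dominant epistasis?
chi_square_gof(c(67, 22, 7), "12:3:1")
#> Segregation test: observed (67, 22, 7) vs ratio 12:3:1
#>   chi-square = 1.40, df = 2, p = 0.50

## A dominant-epistasis penetrance model and its expected ratio
rt1 <- penetrance_model(c("R", "T1"),
  c("R_ __" = "dotted black", "rr T_" = "tan1", "rr tt" = "red"))
expected_phenotype_ratio(rt1)
#> Expected F2 phenotype ratio: 12:3:1 (dotted black:tan1:red)
classify_epistasis(rt1, c("R", "T1"))
#> [1] "dominant"

## Simulate a 128-plant F2 with a causal locus at ~5 Mb and scan it
map <- uniform_map(c(chr3 = 3e7), spacing_bp = 1e4)
pop <- simulate_f2(map, 128, seed = 42)
pop <- assign_phenotypes(pop,
  penetrance_model("R", c("R_" = "dotted black", "rr" = "green")),
  c(R = "chr3_5005000"))
table(pop$phenotype)
#> dotted black        green
#>          100           28

bulks  <- make_bulks(pop, list(bulk_spec("D-bulk", "dotted black", 18),
                               bulk_spec("G-bulk", "green", 18)), seed = 43)
depths <- sample_bulk_depths(pop, bulks, mean_depth = 83, seed = 44)
track  <- delta_index(compute_snp_index(depths), order = c("G-bulk", "D-bulk"))
windows <- sliding_windows(track, window_bp = 1e6, step_bp = 1e4)
thr <- simulate_null_thresholds(128, c(18, 18), depths = c(60, 83, 100),
                                replicates = 10000, seed = 45)
call_qtl(windows, thr, alpha = 0.01)
#> 1 QTL interval(s):
#>   chr3:0.00-18.26 Mb, peak 4.75 Mb, delta 0.576 (p < 0.01)
```

The peak lands next to the simulated causal locus (5.005 Mb), with the
positive delta confirming that the recessive (green) bulk carries the
high-index allele; with a single 128-plant population the significant
interval is wide, exactly as in real bulked-segregant scans.

A thin command-line wrapper is installed at `exec/seedqtl`
(`seedqtl segtest --counts 67,22,7 --ratio 12:3:1`,
`seedqtl scan --table bulks.tsv ...`); run it without arguments for
usage.

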