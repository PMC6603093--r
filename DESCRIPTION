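Package: seedqtl
Title: Mendelian Segregation, Epistasis and QTL-Seq Bulked-Segregant
    Analysis for F2 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping qualitative traits in F2 intercross
    populations, built around the genetics of watermelon seed coat color.
    Provides multi-locus penetrance models with epistasis and expected
    phenotype-ratio enumeration, chi-square goodness-of-fit tests against
    Mendelian ratios, a QTL-seq bulked-segregant scan (per-site SNP-index,
    delta SNP-index, sliding windows, simulation-based significance
    thresholds and QTL interval calling), marker-phenotype association
    tables, light two-point linkage utilities with the Kosambi map
    function, and a synthetic F2 population and bulk-sequencing simulator
    for desk-scale validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
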