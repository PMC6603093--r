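# Shared fixtures: small penetrance models and simulation helpers.

# dominant epistasis: a dominant R allele masks the second locus (12:3:1)
rt1_model <- function() {
  penetrance_model(c("R", "T1"), c(
    "R_ __" = "dotted black",
    "rr T_" = "tan1",
    "rr tt" = "red"))
}

# recessive epistasis: ww masks the D locus (9:3:4)
wd_model <- function() {
  penetrance_model(c("W", "D"), c(
    "W_ D_" = "flat black",
    "W_ dd" = "dotted black",
    "ww __" = "clump"))
}

# single dominant locus (3:1)
single_model <- function() {
  penetrance_model("R", c("R_" = "dotted black", "rr" = "green"))
}

# two independent dominant loci, four phenotypes (9:3:3:1)
indep_model <- function() {
  penetrance_model(c("A", "B"), c(
    "A_ B_" = "p1", "A_ bb" = "p2", "aa B_" = "p3", "aa bb" = "p4"))
}

# one chromosome, markers every `spacing` bp
one_chrom_map <- function(length_bp = 3e7, spacing = 1e4, ...) {
  uniform_map(c(chr1 = length_bp), spacing_bp = spacing, ...)
}

# Brute-force oracle for expected F2 ratios: enumerate all 4^k ordered
# gamete pairs (each equally likely) and classify the resulting genotypes.
# Independent of the 3^k class enumeration used by the package.
gamete_pair_ratio <- function(model, segregating = model$loci$name,
                              fixed_dom = NULL) {
  k <- length(segregating)
  gametes <- as.matrix(expand.grid(rep(list(0:1), k)))  # 1 = dominant allele
  counts <- integer(0)
  for (i in seq_len(nrow(gametes))) for (j in seq_len(nrow(gametes))) {
    dom <- matrix(NA_integer_, 1, nrow(model$loci),
                  dimnames = list(NULL, model$loci$name))
    dom[1, segregating] <- gametes[i, ] + gametes[j, ]
    for (loc in setdiff(model$loci$name, segregating))
      dom[1, loc] <- if (!is.null(fixed_dom) && loc %in% names(fixed_dom))
        fixed_dom[[loc]] else 2L
    p <- classify_genotype(model, dom)
    counts[p] <- (if (p %in% names(counts)) counts[[p]] else 0L) + 1L
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic F2 population with explicit genotypes (B-allele counts)
manual_pop <- function(geno, map) {
  structure(list(map = map, geno = geno, phenotype = NULL,
                 provenance = list(seed = NA, n = nrow(geno))),
            class = "f2_pop")
}

# build a marker_calls table from per-class (genotype, phenotype, count)
# triples; genotype "x:y" is split into alleles
calls_from_counts <- function(...) {
  rows <- list(...)
  g <- unlist(lapply(rows, function(r) rep(r[[1]], r[[3]])))
  p <- unlist(lapply(rows, function(r) rep(r[[2]], r[[3]])))
  al <- strsplit(g, ":", fixed = TRUE)
  marker_calls(seq_along(g), vapply(al, `[`, "", 1), vapply(al, `[`, "", 2),
               p)
}

# fabricate a null_thresholds object with a flat absolute threshold
flat_thresholds <- function(abs_thr, alpha = 0.01, depth = 80) {
  structure(list(
    table = data.frame(depth = depth, alpha = alpha,
                       lower = -abs_thr, upper = abs_thr,
                       abs_threshold = abs_thr),
    params = list(pop_size = NA, bulk_sizes = c(NA, NA), depths = depth,
                  alphas = alpha, replicates = NA, seed = NA)),
    class = "null_thresholds")
}
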