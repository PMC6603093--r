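# Synthetic F2 intercross populations and bulk sequencing.
#
# Allele coding: at every marker, allele "B" is the allele carried by the
# recessive-phenotype parent.  f2_pop$geno stores the count of B alleles
# (0 = AA, 1 = AB, 2 = BB), so the dominant-allele count is 2 - geno and
# the recessive bulk's SNP-index tends to 1 over a causal locus.

#' Define a genetic map for simulation
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp, or
#'   a data frame with columns `chrom` and `length_bp`.
#' @param markers Data frame with columns `chrom`, `pos` (1-based bp) and
#'   `name`; positions must be strictly increasing within a chromosome.
#' @param map_function `"kosambi"` (default) or `"haldane"`; used to turn
#'   inter-marker cM distances into recombination fractions.
#' @param bp_per_cM Physical-to-genetic scale. The default 300 kb/cM is in
#'   the range of compact plant genomes such as watermelon (about 365 Mb
#'   spanning roughly 1200 cM).
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(chromosomes, markers,
                        map_function = c("kosambi", "haldane"),
                        bp_per_cM = 3e5) {
  map_function <- match.arg(map_function)
  if (!is.data.frame(chromosomes))
    chromosomes <- data.frame(chrom = names(chromosomes),
                              length_bp = as.numeric(chromosomes),
                              stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length_bp") %in% names(chromosomes)),
            all(c("chrom", "pos", "name") %in% names(markers)),
            bp_per_cM > 0)
  if (anyDuplicated(markers$name)) stop("marker names must be unique")
  if (!all(markers$chrom %in% chromosomes$chrom))
    stop("markers reference unknown chromosomes")
  markers <- markers[order(match(markers$chrom, chromosomes$chrom),
                           markers$pos), , drop = FALSE]
  rownames(markers) <- NULL
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("marker positions must be strictly increasing on %s", ch))
    len <- chromosomes$length_bp[chromosomes$chrom == ch]
    if (p[1] < 1 || p[length(p)] > len)
      stop(sprintf("marker positions outside chromosome %s", ch))
  }
  structure(list(chromosomes = chromosomes, markers = markers,
                 map_function = map_function, bp_per_cM = bp_per_cM),
            class = "genetic_map")
}

#' Evenly spaced markers for a set of chromosomes
#'
#' Convenience constructor: one marker every `spacing_bp`, starting at
#' `spacing_bp/2`.
#'
#' @inheritParams genetic_map
#' @param spacing_bp Marker spacing in bp.
#' @export
uniform_map <- function(chromosomes, spacing_bp = 1e4, ...) {
  if (!is.data.frame(chromosomes))
    chromosomes <- data.frame(chrom = names(chromosomes),
                              length_bp = as.numeric(chromosomes),
                              stringsAsFactors = FALSE)
  markers <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    pos <- seq(from = max(1, round(spacing_bp / 2)),
               to = chromosomes$length_bp[i], by = spacing_bp)
    data.frame(chrom = chromosomes$chrom[i], pos = pos,
               name = sprintf("%s_%d", chromosomes$chrom[i], pos),
               stringsAsFactors = FALSE)
  }))
  genetic_map(chromosomes, markers, ...)
}

map_rf <- function(d_cM, map_function) {
  switch(map_function,
         kosambi = inverse_kosambi(d_cM),
         haldane = inverse_haldane(d_cM))
}

#' Simulate an F2 intercross population
#'
#' Each individual is formed from two independent gametes.  Along a
#' chromosome a gamete is a Markov chain over parental origin: the allele
#' at the first marker is drawn uniformly, and between adjacent markers the
#' origin switches with the recombination fraction implied by the map
#' function and the inter-marker distance.  Chromosomes assort
#' independently.
#'
#' @param map A [genetic_map()].
#' @param n Number of F2 individuals (>= 1).
#' @param seed Optional integer; if given, `set.seed(seed)` is called so
#'   the population is reproducible.
#' @return An object of class `f2_pop`: list with `map`, `geno` (an
#'   `n x markers` integer matrix of recessive-parent ("B") allele counts,
#'   0/1/2) and `phenotype` (filled by [assign_phenotypes()]).
#' @export
simulate_f2 <- function(map, n, seed = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  mk <- map$markers
  geno <- matrix(0L, n, nrow(mk), dimnames = list(NULL, mk$name))
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    m <- length(idx)
    # 2n gametes simulated jointly, one column per marker
    g <- matrix(0L, 2L * n, m)
    g[, 1] <- rbinom(2L * n, 1L, 0.5)
    if (m > 1) {
      r <- map_rf(diff(mk$pos[idx]) / map$bp_per_cM, map$map_function)
      for (j in 2:m) {
        sw <- rbinom(2L * n, 1L, r[j - 1])
        g[, j] <- (g[, j - 1] + sw) %% 2L
      }
    }
    geno[, idx] <- g[1:n, , drop = FALSE] +
      g[(n + 1):(2L * n), , drop = FALSE]
  }
  structure(list(map = map, geno = geno, phenotype = NULL,
                 provenance = list(seed = seed, n = n)),
            class = "f2_pop")
}

#' @export
print.f2_pop <- function(x, ...) {
  cat(sprintf("F2 population: %d individuals, %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), nrow(x$map$chromosomes)))
  if (!is.null(x$phenotype)) {
    cat("Phenotypes:\n")
    print(table(x$phenotype))
  }
  invisible(x)
}

#' Assign phenotypes to an F2 population under a penetrance model
#'
#' @param pop An [simulate_f2()] population.
#' @param model A [penetrance_model()].
#' @param causal_markers Named character vector mapping each model locus
#'   name to the marker that carries it, e.g. `c(R = "chr3_5000000")`.
#' @return `pop` with `phenotype` filled and the causal-marker assignment
#'   recorded.
#' @export
assign_phenotypes <- function(pop, model, causal_markers) {
  stopifnot(inherits(pop, "f2_pop"), inherits(model, "penetrance_model"))
  if (is.null(names(causal_markers)) ||
      !setequal(names(causal_markers), model$loci$name))
    stop("causal_markers must be named by all model loci")
  missing <- setdiff(causal_markers, colnames(pop$geno))
  if (length(missing))
    stop("causal markers not in map: ", paste(missing, collapse = ", "))
  dom <- 2L - pop$geno[, causal_markers[model$loci$name], drop = FALSE]
  colnames(dom) <- model$loci$name
  pop$phenotype <- classify_genotype(model, dom)
  pop$causal_markers <- causal_markers
  pop
}

#' Specify a phenotype-selected bulk
#'
#' @param label Bulk name, e.g. `"D-bulk"`.
#' @param phenotypes Phenotype labels eligible for the bulk.
#' @param size Number of individuals to pool.
#' @export
bulk_spec <- function(label, phenotypes, size) {
  stopifnot(is.character(label), length(label) == 1,
            is.character(phenotypes), length(phenotypes) >= 1,
            is.numeric(size), size >= 1)
  structure(list(label = label, phenotypes = phenotypes,
                 size = as.integer(size)), class = "bulk_spec")
}

#' Select phenotype bulks from a phenotyped population
#'
#' Members are sampled uniformly without replacement among individuals
#' whose phenotype is in the [bulk_spec()] selector, mirroring pooling
#' equal amounts of DNA from phenotyped plants.
#'
#' @param pop A phenotyped `f2_pop`.
#' @param specs List of [bulk_spec()]s.
#' @param seed Optional integer seed.
#' @return Named list of integer index vectors (one per bulk).
#' @export
make_bulks <- function(pop, specs, seed = NULL) {
  stopifnot(inherits(pop, "f2_pop"))
  if (is.null(pop$phenotype)) stop("population has no phenotypes; run assign_phenotypes() first")
  if (inherits(specs, "bulk_spec")) specs <- list(specs)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(specs, function(sp) {
    eligible <- which(pop$phenotype %in% sp$phenotypes)
    if (length(eligible) < sp$size)
      stop(sprintf("bulk '%s': %d individuals requested but only %d eligible",
                   sp$label, sp$size, length(eligible)))
    sort(if (length(eligible) == 1L) eligible
         else sample(eligible, sp$size))
  })
  names(out) <- vapply(specs, `[[`, "", "label")
  out
}

#' Simulate pooled sequencing depths for two bulks
#'
#' For each marker and bulk, the true alternate-allele (recessive-parent
#' allele) frequency is the allele count among the bulk members' 2m
#' alleles.  Total depth is Poisson with the given mean; alternate reads
#' are binomial with success probability `q(1-e) + (1-q)e`, where `e` is
#' the per-read error rate.
#'
#' @param pop An `f2_pop`.
#' @param bulks Named list of exactly two index vectors from
#'   [make_bulks()].
#' @param mean_depth Mean sequencing depth per bulk (default 83, a typical
#'   whole-genome bulk depth).
#' @param error_rate Per-read error probability in `[0, 0.5)`.
#' @param seed Optional integer seed.
#' @return A [bulk_depth_table()].
#' @export
sample_bulk_depths <- function(pop, bulks, mean_depth = 83,
                               error_rate = 0.005, seed = NULL) {
  stopifnot(inherits(pop, "f2_pop"), mean_depth > 0,
            error_rate >= 0, error_rate < 0.5)
  if (length(bulks) != 2L || is.null(names(bulks)))
    stop("exactly two named bulks are required")
  if (any(lengths(bulks) == 0)) stop("empty bulk")
  if (!is.null(seed)) set.seed(seed)
  mk <- pop$map$markers
  M <- nrow(mk)
  depths <- lapply(bulks, function(idx) {
    q <- colSums(pop$geno[idx, , drop = FALSE]) / (2 * length(idx))
    p_alt <- q * (1 - error_rate) + (1 - q) * error_rate
    total <- rpois(M, mean_depth)
    alt <- rbinom(M, total, p_alt)
    cbind(ref = total - alt, alt = alt)
  })
  bulk_depth_table(chrom = mk$chrom, pos = mk$pos,
                   ref_a = depths[[1]][, "ref"], alt_a = depths[[1]][, "alt"],
                   ref_b = depths[[2]][, "ref"], alt_b = depths[[2]][, "alt"],
                   bulk_names = names(bulks))
}

#' Per-position allele depths for two phenotype bulks
#'
#' The core input of the QTL-seq scan: for every genomic position, the
#' reference and alternate read depths observed in each of two
#' phenotype-selected bulks.  By simulator convention the alternate allele
#' is the recessive-phenotype parent's allele.
#'
#' @param chrom,pos Chromosome labels and 1-based positions.
#' @param ref_a,alt_a,ref_b,alt_b Non-negative integer depths for the two
#'   bulks.
#' @param bulk_names Length-2 character vector naming the bulks.
#' @return Data frame of class `bulk_depth_table` with attribute
#'   `bulk_names`.
#' @export
bulk_depth_table <- function(chrom, pos, ref_a, alt_a, ref_b, alt_b,
                             bulk_names = c("bulk_a", "bulk_b")) {
  d <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref_a = as.integer(ref_a), alt_a = as.integer(alt_a),
                  ref_b = as.integer(ref_b), alt_b = as.integer(alt_b),
                  stringsAsFactors = FALSE)
  if (any(d[, 3:6] < 0, na.rm = TRUE)) stop("depths must be non-negative")
  stopifnot(length(bulk_names) == 2)
  d <- d[order(match(d$chrom, unique(d$chrom)), d$pos), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, bulk_names = as.character(bulk_names),
            class = c("bulk_depth_table", "data.frame"))
}

#' @export
print.bulk_depth_table <- function(x, ...) {
  bn <- attr(x, "bulk_names")
  cat(sprintf("Bulk depth table: %d positions, bulks %s / %s\n",
              nrow(x), bn[1], bn[2]))
  print.data.frame(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
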