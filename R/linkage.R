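# Light linkage utilities: map functions, phenotype-to-marker coding with
# epistatic masking, marker QC, and two-point recombination estimation.

#' Kosambi and Haldane map functions
#'
#' `kosambi(r)` converts a recombination fraction to centimorgans,
#' `d = 25 * log((1 + 2r) / (1 - 2r))`; `inverse_kosambi(d)` inverts it with
#' `(exp(d/25) - 1) / (2 * (exp(d/25) + 1))`.  The Haldane pair uses
#' `d = -50 * log(1 - 2r)`.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in cM, `>= 0`.
#' @return Numeric vector (cM for the forward functions, recombination
#'   fraction for the inverses).
#' @examples
#' kosambi(0.25)                   # 25 * log(3) = 27.465 cM
#' inverse_kosambi(kosambi(0.1))   # 0.1
#' @export
kosambi <- function(r) {
  check_rf(r)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
inverse_kosambi <- function(d) {
  stopifnot(all(d >= 0))
  (exp(d / 25) - 1) / (2 * (exp(d / 25) + 1))
}

#' @rdname kosambi
#' @export
haldane <- function(r) {
  check_rf(r)
  -50 * log(1 - 2 * r)
}

#' @rdname kosambi
#' @export
inverse_haldane <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d / 100)) / 2
}

check_rf <- function(r) {
  if (any(r < 0) || any(r >= 0.5))
    stop("recombination fractions must lie in [0, 0.5)")
  invisible(r)
}

# "abhcd" code semantics, expressed as sets of parent-B allele counts:
#   a = parent-A homozygote (0), h = heterozygote (1), b = parent-B
#   homozygote (2), c = not-a (1 or 2), d = not-b (0 or 1).
code_states <- list(a = 0L, h = 1L, b = 2L, c = c(1L, 2L), d = c(0L, 1L))

#' Encode phenotypes as an "abhcd" marker for one locus
#'
#' Translates phenotype labels into the JoinMap-style F2 genotype codes for
#' a single locus of a penetrance model: a phenotype class maps to the set
#' of locus genotypes compatible with it, and that set determines the code
#' (`a`/`h`/`b` when the genotype is determined, `c` = not-a, `d` = not-b).
#' Phenotype classes in which the locus is epistatically masked (all three
#' genotypes possible, or an uncodable set) become missing (`NA`) — e.g.
#' clump-seeded individuals carry no information about the `D` locus.
#'
#' @param phenotypes Character vector of individual phenotype labels.
#' @param locus Locus name in `model`.
#' @param model A [penetrance_model()].
#' @param segregating Loci segregating in the population (default: all).
#' @param fixed Concrete states of non-segregating loci, as in
#'   [expected_phenotype_ratio()].
#' @param parent_a `"dominant"` if parent A is the dominant homozygote at
#'   this locus, `"recessive"` otherwise.  Determines which homozygote is
#'   coded `a`.
#' @return Character vector of codes in `{a, h, b, c, d}` with `NA` for
#'   masked phenotypes, of class `coded_marker`.
#' @examples
#' m <- penetrance_model(c("W", "D"),
#'   c("W_ D_" = "flat black", "W_ dd" = "dotted black", "ww __" = "clump"))
#' # D locus: clump individuals are masked, flat black = not-a
#' encode_phenotype_marker(c("flat black", "dotted black", "clump"),
#'                         "D", m, parent_a = "recessive")
#' @export
encode_phenotype_marker <- function(phenotypes, locus, model,
                                    segregating = model$loci$name,
                                    fixed = NULL,
                                    parent_a = c("dominant", "recessive")) {
  parent_a <- match.arg(parent_a)
  stopifnot(locus %in% model$loci$name, locus %in% segregating)
  fixed_states <- resolve_fixed(model, fixed)
  k <- length(segregating)
  grid <- as.matrix(expand.grid(rep(list(0:2), k)))
  dom <- matrix(NA_integer_, nrow(grid), nrow(model$loci),
                dimnames = list(NULL, model$loci$name))
  dom[, segregating] <- grid
  for (loc in setdiff(model$loci$name, segregating))
    dom[, loc] <- if (loc %in% names(fixed_states)) fixed_states[[loc]] else 2L
  phen <- classify_genotype(model, dom)
  known <- unique(phen)
  bad <- setdiff(unique(phenotypes[!is.na(phenotypes)]), known)
  if (length(bad))
    stop("phenotype label(s) not produced by the model: ",
         paste(bad, collapse = ", "))
  # genotype states (parent-B allele counts) compatible with each phenotype
  to_b_count <- function(dom_state) {
    if (parent_a == "dominant") 2L - dom_state else dom_state
  }
  code_of <- vapply(known, function(p) {
    states <- sort(unique(to_b_count(dom[phen == p, locus])))
    hit <- vapply(code_states, function(s) identical(sort(s), states),
                  logical(1))
    if (any(hit)) names(code_states)[which(hit)[1]] else NA_character_
  }, character(1))
  out <- unname(code_of[match(phenotypes, known)])
  structure(out, locus = locus, parent_a = parent_a,
            class = c("coded_marker", class(out)))
}

#' Marker quality control: missing data and segregation distortion
#'
#' Drops markers with more than `max_missing` missing calls or with
#' segregation distortion at `p < distortion_alpha` against the 1:2:1 F2
#' expectation ([distortion_test()]).
#'
#' @param geno Matrix or data frame, individuals x markers, with
#'   codominant calls coded `"AA"/"AB"/"BB"` (or `"a"/"h"/"b"`); missing as
#'   `NA` or `"-"`.
#' @param max_missing Maximum tolerated missing fraction (default 0.20).
#' @param distortion_alpha Distortion significance cut-off (default 1e-4).
#' @return Object of class `marker_qc`: `retained` (marker names) and
#'   `report` (per-marker data frame).
#' @export
marker_qc <- function(geno, max_missing = 0.20, distortion_alpha = 1e-4) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("M", seq_len(ncol(geno)))
  geno[geno == "-"] <- NA
  recode <- c(AA = "a", AB = "h", BB = "b", a = "a", h = "h", b = "b")
  report <- do.call(rbind, lapply(colnames(geno), function(m) {
    calls <- recode[geno[, m]]
    n <- length(calls)
    miss <- mean(is.na(calls))
    counts <- c(a = sum(calls == "a", na.rm = TRUE),
                h = sum(calls == "h", na.rm = TRUE),
                b = sum(calls == "b", na.rm = TRUE))
    dt <- if (sum(counts) > 0)
      suppressMessages(distortion_test(counts, distortion_alpha)) else NULL
    data.frame(marker = m, n = n, missing_frac = miss,
               chi_square = if (is.null(dt)) NA_real_ else dt$statistic,
               p_value = if (is.null(dt)) NA_real_ else dt$p.value,
               fail_missing = miss > max_missing,
               fail_distortion = if (is.null(dt)) TRUE else dt$distorted,
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  retained <- report$marker[!report$fail_missing & !report$fail_distortion]
  structure(list(retained = retained, report = report,
                 max_missing = max_missing,
                 distortion_alpha = distortion_alpha),
            class = "marker_qc")
}

#' @export
print.marker_qc <- function(x, ...) {
  cat(sprintf("Marker QC: %d of %d markers retained (max missing %.0f%%, distortion alpha %g)\n",
              length(x$retained), nrow(x$report),
              100 * x$max_missing, x$distortion_alpha))
  invisible(x)
}

# Joint F2 genotype probabilities for two loci in coupling at
# recombination fraction r; cells indexed by parent-B allele counts
# (0,1,2) x (0,1,2).  Vectorised over r: returns a length(r) x 9 matrix,
# columns in order (g1,g2) = (0,0),(1,0),(2,0),(0,1),(1,1),(2,1),...
f2_joint_probs <- function(r) {
  s <- 1 - r
  cbind(s^2 / 4, s * r / 2, r^2 / 4,
        s * r / 2, (s^2 + r^2) / 2, s * r / 2,
        r^2 / 4, s * r / 2, s^2 / 4)
}

#' Two-point recombination fraction between F2 markers
#'
#' Maximum-likelihood estimate of the recombination fraction between two
#' markers scored in "abhcd" codes on the same F2 individuals, assuming
#' coupling phase.  The likelihood marginalises dominant codes (`c` =
#' not-a, `d` = not-b) over their compatible genotypes, so
#' codominant x codominant, codominant x dominant and dominant x dominant
#' pairs are all handled.  The likelihood is maximised over a dense grid
#' on `[0, 0.5)` followed by local refinement; estimates at the unlinked
#' boundary are capped at 0.499 so the map distance stays finite.
#'
#' @param x,y Character vectors of codes in `{a, h, b, c, d}` (missing as
#'   `NA` or `"-"`), same individuals in the same order.
#' @param map_function `"kosambi"` (default) or `"haldane"` for the cM
#'   conversion.
#' @param grid_step Grid resolution for the likelihood scan.
#' @return Object of class `map_distance`: `r`, `cM`, `map_function`, `n`
#'   (jointly scored individuals), `loglik`.
#' @examples
#' x <- c("a", "h", "b", "h", "a")
#' estimate_rf(x, x)   # identical markers: r = 0
#' @export
estimate_rf <- function(x, y, map_function = c("kosambi", "haldane"),
                        grid_step = 1e-4) {
  map_function <- match.arg(map_function)
  stopifnot(length(x) == length(y))
  x[x == "-"] <- NA; y[y == "-"] <- NA
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0) stop("no jointly scored individuals")
  if (n < 30)
    warning(sprintf("only %d jointly scored individuals; estimate may be unstable", n))
  x <- x[ok]; y <- y[ok]
  bad <- setdiff(unique(c(x, y)), names(code_states))
  if (length(bad)) stop("unknown genotype codes: ", paste(bad, collapse = ", "))
  # count individuals per observed code pair
  pair <- table(x, y)
  # admissibility of each of the 9 genotype cells for each code
  cell_in <- function(code, g) g %in% code_states[[code]]
  r_grid <- seq(0, 0.4999, by = grid_step)
  P <- f2_joint_probs(r_grid)           # length(grid) x 9
  ll <- numeric(length(r_grid))
  for (cx in rownames(pair)) for (cy in colnames(pair)) {
    nij <- pair[cx, cy]
    if (nij == 0) next
    cols <- which(outer(0:2, 0:2,
                        function(g1, g2) cell_in(cx, g1) & cell_in(cy, g2)))
    S <- if (length(cols) == 1) P[, cols] else rowSums(P[, cols, drop = FALSE])
    ll <- ll + nij * log(pmax(S, 1e-300))
  }
  i <- which.max(ll)
  lo <- r_grid[max(1, i - 1)]; hi <- r_grid[min(length(r_grid), i + 1)]
  obj <- function(r) {
    p <- f2_joint_probs(r)
    tot <- 0
    for (cx in rownames(pair)) for (cy in colnames(pair)) {
      nij <- pair[cx, cy]
      if (nij == 0) next
      cols <- which(outer(0:2, 0:2,
                          function(g1, g2) cell_in(cx, g1) & cell_in(cy, g2)))
      tot <- tot + nij * log(pmax(sum(p[1, cols]), 1e-300))
    }
    tot
  }
  r_hat <- if (hi > lo)
    optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-8)$maximum
  else lo
  if (obj(r_grid[i]) > obj(r_hat)) r_hat <- r_grid[i]
  r_hat <- min(r_hat, 0.499)
  d <- switch(map_function, kosambi = kosambi(r_hat), haldane = haldane(r_hat))
  structure(list(r = r_hat, cM = d, map_function = map_function,
                 n = n, loglik = obj(r_hat)),
            class = "map_distance")
}

#' @export
print.map_distance <- function(x, ...) {
  cat(sprintf("Two-point estimate: r = %.4f, %.1f cM (%s), n = %d\n",
              x$r, x$cM, x$map_function, x$n))
  invisible(x)
}
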