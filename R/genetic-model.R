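# Multi-locus penetrance models for qualitative F2 traits.
#
# Genotypes at a locus are stored internally as the count of *dominant*
# alleles: 2 = homozygous dominant, 1 = heterozygous, 0 = homozygous
# recessive.  Rule patterns use the classical shorthand built from the
# first letter of the locus name: "RR", "Rr", "rr", the dominant-carrier
# wildcard "R_", and "__" (or "*") for any genotype.

STATE_ANY <- 0:2
STATE_CARRIER <- 1:2

#' Define a multi-locus penetrance model
#'
#' A penetrance model maps multi-locus F2 genotype classes to phenotype
#' labels.  Rules are evaluated in order and the first matching rule wins,
#' which is the natural way to express epistasis ("a dominant `R` allele
#' gives dotted black seed regardless of the `T` genotype").
#'
#' @param loci Character vector of locus names (e.g. `c("R", "T1")`), or a
#'   data frame with columns `name` and optionally `chromosome`,
#'   `position_bp` and `dominance_note`.  Locus names must be unique and
#'   must start with distinct letters, since rule patterns refer to loci by
#'   their initial letter.
#' @param rules Named character vector: names are genotype-class patterns,
#'   values are phenotype labels.  A pattern has one whitespace-separated
#'   token per locus, in the order of `loci`.  Tokens: `"RR"` homozygous
#'   dominant, `"Rr"` heterozygous, `"rr"` homozygous recessive, `"R_"`
#'   dominant carrier (RR or Rr), and `"__"` or `"*"` for any genotype.
#' @param default_phenotype Optional label assigned to concrete genotype
#'   classes not covered by any rule.  If `NULL` (default), classifying an
#'   uncovered class is an error naming the class.
#'
#' @return An object of class `penetrance_model`.
#' @examples
#' m <- penetrance_model(c("R", "T1"),
#'   c("R_ __" = "dotted black", "rr T_" = "tan1", "rr tt" = "red"))
#' expected_phenotype_ratio(m)     # 12:3:1
#' classify_epistasis(m, c("R", "T1"))
#' @seealso [expected_phenotype_ratio()], [classify_epistasis()],
#'   [seed_coat_model()], [read_penetrance_model()]
#' @export
penetrance_model <- function(loci, rules, default_phenotype = NULL) {
  if (is.character(loci)) {
    loci <- data.frame(name = loci, chromosome = NA_character_,
                       position_bp = NA_integer_,
                       dominance_note = NA_character_,
                       stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(loci), "name" %in% names(loci))
  for (col in c("chromosome", "position_bp", "dominance_note"))
    if (!col %in% names(loci)) loci[[col]] <- NA
  if (anyDuplicated(loci$name))
    stop("locus names must be unique")
  if (any(!is.na(loci$position_bp) & loci$position_bp < 1))
    stop("position_bp must be >= 1 when set")
  symbols <- toupper(substr(loci$name, 1L, 1L))
  if (anyDuplicated(symbols))
    stop("locus names must start with distinct letters (patterns refer to loci by initial letter)")
  if (is.null(names(rules)) || any(!nzchar(names(rules))))
    stop("'rules' must be a named character vector (pattern -> phenotype)")
  parsed <- lapply(names(rules), parse_pattern, symbols = symbols)
  model <- structure(list(
    loci = loci,
    symbols = symbols,
    rules = lapply(seq_along(rules), function(i)
      list(pattern = names(rules)[i], states = parsed[[i]],
           phenotype = unname(rules[i]))),
    default_phenotype = default_phenotype,
    phenotypes = unique(c(unname(rules), default_phenotype))
  ), class = "penetrance_model")
  model
}

# Parse one rule pattern into a list of admissible dominant-allele-count
# sets, one per locus.
parse_pattern <- function(pattern, symbols) {
  tokens <- strsplit(trimws(pattern), "\\s+")[[1]]
  if (length(tokens) != length(symbols))
    stop(sprintf("pattern '%s' has %d tokens but the model has %d loci",
                 pattern, length(tokens), length(symbols)))
  Map(parse_state_token, tokens, symbols, MoreArgs = list(pattern = pattern))
}

parse_state_token <- function(token, symbol, pattern) {
  if (token %in% c("*", "**", "__", "..", "--", "any")) return(STATE_ANY)
  chars <- strsplit(token, "")[[1]]
  if (length(chars) != 2L || toupper(chars[1]) != symbol ||
      !(chars[2] == "_" || toupper(chars[2]) == symbol))
    stop(sprintf("cannot parse token '%s' for locus '%s' in pattern '%s'",
                 token, symbol, pattern))
  upper1 <- chars[1] == toupper(chars[1])
  if (chars[2] == "_") {
    if (!upper1)
      stop(sprintf("token '%s': the carrier wildcard needs an uppercase letter", token))
    return(STATE_CARRIER)
  }
  upper2 <- chars[2] == toupper(chars[2])
  sum(upper1, upper2)  # 2, 1 or 0 dominant alleles
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("Penetrance model: %d loci (%s), %d rules\n",
              nrow(x$loci), paste(x$loci$name, collapse = ", "),
              length(x$rules)))
  for (r in x$rules)
    cat(sprintf("  %-20s -> %s\n", r$pattern, r$phenotype))
  if (!is.null(x$default_phenotype))
    cat(sprintf("  %-20s -> %s\n", "<default>", x$default_phenotype))
  invisible(x)
}

# Human-readable name of a concrete genotype class, e.g. "RR Tt ww".
format_class <- function(dom_counts, symbols) {
  paste(mapply(function(d, s) {
    lo <- tolower(s)
    c(paste0(lo, lo), paste0(s, lo), paste0(s, s))[d + 1L]
  }, dom_counts, symbols), collapse = " ")
}

#' Classify multi-locus genotypes under a penetrance model
#'
#' @param model A [penetrance_model()].
#' @param dom_counts Integer matrix (individuals x loci) of dominant-allele
#'   counts (0, 1 or 2); columns in the order of `model$loci`, or named by
#'   locus.
#' @return Character vector of phenotype labels.
#' @export
classify_genotype <- function(model, dom_counts) {
  if (is.null(dim(dom_counts)))
    dom_counts <- matrix(dom_counts, nrow = 1)
  if (!is.null(colnames(dom_counts)))
    dom_counts <- dom_counts[, model$loci$name, drop = FALSE]
  if (ncol(dom_counts) != nrow(model$loci))
    stop("dom_counts must have one column per model locus")
  if (any(is.na(dom_counts)) || any(!dom_counts %in% 0:2))
    stop("dom_counts must contain only 0, 1 or 2")
  phen <- rep(NA_character_, nrow(dom_counts))
  for (r in model$rules) {
    open <- is.na(phen)
    if (!any(open)) break
    hit <- open
    for (j in seq_along(r$states))
      hit <- hit & dom_counts[, j] %in% r$states[[j]]
    phen[hit] <- r$phenotype
  }
  if (anyNA(phen)) {
    if (!is.null(model$default_phenotype)) {
      phen[is.na(phen)] <- model$default_phenotype
    } else {
      i <- which(is.na(phen))[1]
      stop(sprintf("genotype class '%s' is not covered by any rule",
                   format_class(dom_counts[i, ], model$symbols)))
    }
  }
  phen
}

# Resolve the `fixed` argument (named tokens like c(W = "WW") or named
# dominant-allele counts) to a named integer vector of concrete states.
resolve_fixed <- function(model, fixed) {
  if (is.null(fixed)) return(integer(0))
  nm <- names(fixed)
  if (is.null(nm) || !all(nm %in% model$loci$name))
    stop("'fixed' must be named by model loci")
  out <- integer(length(fixed))
  for (i in seq_along(fixed)) {
    v <- fixed[[i]]
    if (is.numeric(v)) {
      stopifnot(v %in% 0:2)
      out[i] <- as.integer(v)
    } else {
      sym <- model$symbols[match(nm[i], model$loci$name)]
      st <- parse_state_token(v, sym, pattern = v)
      if (length(st) != 1L)
        stop(sprintf("fixed state '%s' for locus %s is not concrete", v, nm[i]))
      out[i] <- st
    }
  }
  names(out) <- nm
  out
}

#' Expected F2 phenotype ratio under a penetrance model
#'
#' Enumerates the 3^k concrete genotype classes of the segregating loci
#' with their F2 frequencies (1:2:1 per locus, multiplied across loci,
#' assuming independent assortment), classifies each class, and sums
#' frequencies per phenotype.  Weights are returned both raw (summing to
#' 4^k) and reduced by their greatest common divisor, so that a
#' dominant-epistasis model prints as `12:3:1`.
#'
#' @param model A [penetrance_model()].
#' @param segregating Character vector of segregating locus names (default:
#'   all model loci).
#' @param fixed Named vector giving the concrete genotype of the
#'   non-segregating loci, as pattern tokens (`c(W = "WW", D = "dd")`) or
#'   dominant-allele counts.  Loci neither segregating nor in `fixed` are
#'   fixed homozygous dominant.
#' @return An object of class `phenotype_ratio` with elements `labels`,
#'   `weights` (reduced), `raw_weights` and `total` (= 4^k).
#' @examples
#' m <- penetrance_model(c("W", "D"),
#'   c("W_ D_" = "flat black", "W_ dd" = "dotted black", "ww __" = "clump"))
#' expected_phenotype_ratio(m)   # 9:3:4
#' @export
expected_phenotype_ratio <- function(model, segregating = model$loci$name,
                                     fixed = NULL) {
  stopifnot(all(segregating %in% model$loci$name))
  fixed <- resolve_fixed(model, fixed)
  if (length(intersect(names(fixed), segregating)))
    stop("a locus cannot be both segregating and fixed")
  k <- length(segregating)
  if (k == 0) stop("at least one segregating locus is required")
  grid <- as.matrix(expand.grid(rep(list(0:2), k)))
  # F2 class weight out of 4 per locus: hom 1, het 2
  w <- apply(grid, 1, function(g) prod(ifelse(g == 1L, 2L, 1L)))
  dom <- matrix(NA_integer_, nrow(grid), nrow(model$loci),
                dimnames = list(NULL, model$loci$name))
  dom[, segregating] <- grid
  rest <- setdiff(model$loci$name, segregating)
  for (loc in rest)
    dom[, loc] <- if (loc %in% names(fixed)) fixed[[loc]] else 2L
  phen <- classify_genotype(model, dom)
  labels <- unique(phen[order(match(phen, vapply(model$rules, `[[`, "",
                                                "phenotype")))])
  raw <- vapply(labels, function(p) sum(w[phen == p]), numeric(1))
  g <- Reduce(gcd2, raw)
  structure(list(labels = labels, weights = as.integer(raw / g),
                 raw_weights = as.integer(raw), total = 4L^k),
            class = "phenotype_ratio")
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' @export
format.phenotype_ratio <- function(x, ...) {
  paste0(paste(x$weights, collapse = ":"),
         " (", paste(x$labels, collapse = ":"), ")")
}

#' @export
print.phenotype_ratio <- function(x, ...) {
  cat("Expected F2 phenotype ratio:", format(x), "\n")
  invisible(x)
}

#' Classify two-locus epistasis from expected segregation
#'
#' Computes the expected F2 ratio for a pair of segregating loci and
#' matches it against the canonical two-locus patterns: no epistasis
#' (9:3:3:1), dominant epistasis (12:3:1) and recessive epistasis (9:3:4).
#'
#' @inheritParams expected_phenotype_ratio
#' @param locus_pair Character vector of exactly two locus names.
#' @return A character scalar, one of `"none"`, `"dominant"`,
#'   `"recessive"`, `"other"`, with the underlying `phenotype_ratio`
#'   attached as attribute `"ratio"`.
#' @export
classify_epistasis <- function(model, locus_pair, fixed = NULL) {
  if (length(locus_pair) != 2L)
    stop("exactly two segregating loci are required")
  ratio <- expected_phenotype_ratio(model, locus_pair, fixed)
  sw <- sort(ratio$weights, decreasing = TRUE)
  label <-
    if (identical(sw, c(9L, 3L, 3L, 1L))) "none"
    else if (identical(sw, c(12L, 3L, 1L))) "dominant"
    else if (identical(sw, c(9L, 4L, 3L))) "recessive"
    else "other"
  structure(label, ratio = ratio)
}

#' The four-gene watermelon seed-coat-color model
#'
#' The classical model in which three color genes `R`, `T` and `W` and a
#' modifier `D` (acting only when `R`, `T` and `W` carry a dominant allele)
#' combine to produce flat black (`R_T_W_D_`), dotted black (`R_T_W_dd`),
#' green (`rrT_W_`), tan (`R_ttW_`), clump (`R_T_ww`), red (`rrttW_`) and
#' white tip phenotypes.  The published classes leave `rr T_ ww` unnamed;
#' this implementation folds all `rr .. ww` classes into "white pink-tip"
#' so that the 81 concrete classes are fully partitioned (see the package
#' vignette).
#'
#' The `T1` locus name follows the naming of the tan1/red variant of the
#' `T` gene; only the label differs from `T`.
#'
#' @return A [penetrance_model()] over loci `R`, `T1`, `W`, `D` with
#'   chromosome assignments 3, 5, 6 and 8.
#' @examples
#' m <- seed_coat_model()
#' expected_phenotype_ratio(m, "R")                      # 3:1
#' expected_phenotype_ratio(m, c("R", "T1"))             # 12:3:1
#' expected_phenotype_ratio(m, c("W", "D"),
#'                          fixed = c(R = "RR", T1 = "TT"))  # 9:3:4
#' @export
seed_coat_model <- function() {
  loci <- data.frame(
    name = c("R", "T1", "W", "D"),
    chromosome = c("3", "5", "6", "8"),
    position_bp = NA_integer_,
    dominance_note = c("dotted black dominant to green/red background",
                       "tan1 dominant to red",
                       "non-clump dominant to clump",
                       "modifier; acts only when R, T and W are dominant"),
    stringsAsFactors = FALSE)
  penetrance_model(loci, c(
    "R_ T_ W_ D_" = "flat black",
    "R_ T_ W_ dd" = "dotted black",
    "rr T_ W_ __" = "green",
    "R_ tt W_ __" = "tan",
    "R_ T_ ww __" = "clump",
    "rr tt W_ __" = "red",
    "R_ tt ww __" = "white tan-tip",
    "rr __ ww __" = "white pink-tip"))
}

#' Read / write a penetrance model as a YAML config
#'
#' The config has keys `loci` (list of `name`, optional `chromosome`,
#' `position_bp`, `dominance_note`), `rules` (ordered list of `pattern`,
#' `phenotype`) and optional `default_phenotype`.
#'
#' @param path File path.
#' @return `read_penetrance_model()` returns a [penetrance_model()];
#'   `write_penetrance_model()` returns `path` invisibly.
#' @export
read_penetrance_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$loci) || is.null(cfg$rules))
    stop("model config needs 'loci' and 'rules'")
  loci <- do.call(rbind, lapply(cfg$loci, function(l)
    data.frame(name = l$name,
               chromosome = l$chromosome %||% NA_character_,
               position_bp = l$position_bp %||% NA_integer_,
               dominance_note = l$dominance_note %||% NA_character_,
               stringsAsFactors = FALSE)))
  rules <- vapply(cfg$rules, `[[`, "", "phenotype")
  names(rules) <- vapply(cfg$rules, `[[`, "", "pattern")
  penetrance_model(loci, rules, default_phenotype = cfg$default_phenotype)
}

#' @rdname read_penetrance_model
#' @param model A [penetrance_model()].
#' @export
write_penetrance_model <- function(model, path) {
  cfg <- list(
    loci = lapply(seq_len(nrow(model$loci)), function(i) {
      l <- as.list(model$loci[i, ])
      l[!vapply(l, function(v) all(is.na(v)), logical(1))]
    }),
    rules = lapply(model$rules, function(r)
      list(pattern = r$pattern, phenotype = r$phenotype)))
  if (!is.null(model$default_phenotype))
    cfg$default_phenotype <- model$default_phenotype
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
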