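# Genotype-phenotype association tables for validation markers
# (e.g. KASP assays): single-marker prediction accuracy, two-marker joint
# tables under an epistasis rule, and the accuracy-vs-recombination report.

# The field reports percentages truncated (not rounded) to 2 decimals:
# 65/71 prints as 91.54, 7/9 as 77.77.
trunc2 <- function(x) trunc(x * 100) / 100

normalize_genotype <- function(g) {
  vapply(strsplit(g, ":", fixed = TRUE), function(a)
    paste(sort(a), collapse = ":"), character(1))
}

#' Build a marker call table
#'
#' @param id Individual identifiers.
#' @param allele1,allele2 Allele calls (e.g. `"G"`, `"T"`); `NA` for
#'   ambiguous/missing calls.
#' @param phenotype Phenotype label per individual.
#' @param marker Marker name.
#' @return Data frame of class `marker_calls` with a normalised `genotype`
#'   column (`"G:T"` and `"T:G"` are the same class).
#' @export
marker_calls <- function(id, allele1, allele2, phenotype, marker = "marker") {
  stopifnot(length(id) == length(allele1), length(id) == length(allele2),
            length(id) == length(phenotype))
  if (anyDuplicated(id)) stop("individual ids must be unique")
  geno <- ifelse(is.na(allele1) | is.na(allele2), NA_character_,
                 normalize_genotype(paste(allele1, allele2, sep = ":")))
  structure(data.frame(id = as.character(id), genotype = geno,
                       phenotype = as.character(phenotype),
                       stringsAsFactors = FALSE),
            marker = marker, class = c("marker_calls", "data.frame"))
}

new_assoc_table <- function(classes, n_missing, n) {
  correct <- sum(vapply(classes, `[[`, 0, "n_correct"))
  overall <- 100 * correct / n
  cls <- do.call(rbind, lapply(classes, function(cl)
    data.frame(class = cl$label, predicted = cl$predicted, n = cl$n,
               n_correct = cl$n_correct,
               accuracy = cl$accuracy, accuracy_2dp = trunc2(cl$accuracy),
               stringsAsFactors = FALSE)))
  rownames(cls) <- NULL
  structure(list(classes = cls,
                 crosstab = do.call(rbind, lapply(classes, `[[`, "counts")),
                 overall_accuracy = overall,
                 overall_accuracy_2dp = trunc2(overall),
                 n = n, n_missing = n_missing),
            class = "assoc_table")
}

#' Single-marker phenotype prediction accuracy
#'
#' Cross-tabulates genotype classes against phenotypes and scores each
#' class's predicted phenotype: class accuracy is the percentage of
#' non-missing individuals in the class showing the predicted phenotype,
#' and overall accuracy is the percentage correctly predicted among all
#' non-missing individuals.  Percentages are reported at full precision
#' and truncated to 2 decimals, the convention used when printing marker
#' validation results.
#'
#' @param calls A [marker_calls()] table; individuals with missing
#'   genotype are excluded from all denominators.
#' @param rule Named list mapping each predicted phenotype to the genotype
#'   classes it covers, e.g.
#'   `list("dotted black" = c("G:G", "T:G"), "green" = "T:T")`.  Carrier
#'   classes pool the dominant homozygote with the heterozygote.  Every
#'   observed non-missing genotype must be covered.
#' @return An object of class `assoc_table`.
#' @examples
#' calls <- marker_calls(1:4, c("G","G","T","T"), c("G","T","T","T"),
#'                       c("dotted black","dotted black","green","dotted black"))
#' single_marker_accuracy(calls,
#'   list("dotted black" = c("G:G", "G:T"), "green" = "T:T"))
#' @export
single_marker_accuracy <- function(calls, rule) {
  stopifnot(inherits(calls, "marker_calls"))
  ok <- !is.na(calls$genotype)
  d <- calls[ok, , drop = FALSE]
  class_geno <- lapply(rule, normalize_genotype)
  covered <- unlist(class_geno, use.names = FALSE)
  if (anyDuplicated(covered))
    stop("rule assigns a genotype to more than one class")
  bad <- setdiff(unique(d$genotype), covered)
  if (length(bad))
    stop("rule does not cover genotype class(es): ",
         paste(bad, collapse = ", "))
  classes <- lapply(names(rule), function(pred) {
    in_class <- d$genotype %in% class_geno[[pred]]
    counts <- table(factor(d$phenotype[in_class],
                           levels = sort(unique(d$phenotype))))
    n <- sum(in_class)
    n_correct <- sum(d$phenotype[in_class] == pred)
    list(label = paste(rule[[pred]], collapse = "|"), predicted = pred,
         n = n, n_correct = n_correct,
         accuracy = if (n > 0) 100 * n_correct / n else NA_real_,
         counts = counts)
  })
  new_assoc_table(classes, n_missing = sum(!ok), n = nrow(d))
}

#' Two-marker joint association table under an epistasis rule
#'
#' Joins two marker call tables by individual id (individuals missing
#' either call are excluded), forms joint genotype classes, and predicts
#' the phenotype of each joint class from an ordered, first-match rule —
#' the natural encoding of epistasis, e.g. "any carrier of the dominant
#' `R` allele is dotted black regardless of the second marker".
#'
#' @param calls_a,calls_b Two [marker_calls()] tables over the same
#'   individuals.
#' @param rule Ordered list of clauses `list(a = <genotype classes or NULL
#'   for any>, b = <genotype classes or NULL>, phenotype = <predicted>)`,
#'   evaluated first-match.
#' @return An object of class `assoc_table`; joint classes are labelled
#'   `"<a classes> / <b classes>"` with `*` for "any".
#' @export
two_marker_table <- function(calls_a, calls_b, rule) {
  stopifnot(inherits(calls_a, "marker_calls"), inherits(calls_b, "marker_calls"))
  m <- merge(calls_a, calls_b, by = "id", suffixes = c("_a", "_b"))
  if (any(m$phenotype_a != m$phenotype_b))
    stop("phenotypes disagree between the two call tables for some ids")
  m <- m[!is.na(m$genotype_a) & !is.na(m$genotype_b), , drop = FALSE]
  if (!nrow(m)) stop("no individuals with calls at both markers")
  assigned <- rep(NA_integer_, nrow(m))
  for (i in seq_along(rule)) {
    cl <- rule[[i]]
    hit <- is.na(assigned) &
      (is.null(cl$a) | m$genotype_a %in% normalize_genotype(cl$a %||% "")) &
      (is.null(cl$b) | m$genotype_b %in% normalize_genotype(cl$b %||% ""))
    assigned[hit] <- i
  }
  if (anyNA(assigned)) {
    j <- which(is.na(assigned))[1]
    stop(sprintf("joint genotype class '%s / %s' is not covered by the rule",
                 m$genotype_a[j], m$genotype_b[j]))
  }
  classes <- lapply(seq_along(rule), function(i) {
    cl <- rule[[i]]
    lab <- paste(
      if (is.null(cl$a)) "*" else paste(cl$a, collapse = "|"),
      if (is.null(cl$b)) "*" else paste(cl$b, collapse = "|"),
      sep = " / ")
    in_class <- assigned == i
    n <- sum(in_class)
    n_correct <- sum(m$phenotype_a[in_class] == cl$phenotype)
    list(label = lab, predicted = cl$phenotype, n = n, n_correct = n_correct,
         accuracy = if (n > 0) 100 * n_correct / n else NA_real_,
         counts = table(factor(m$phenotype_a[in_class],
                               levels = sort(unique(m$phenotype_a)))))
  })
  new_assoc_table(classes,
                  n_missing = length(union(calls_a$id, calls_b$id)) - nrow(m),
                  n = nrow(m))
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("Marker-phenotype association (n = %d scored, %d missing)\n",
              x$n, x$n_missing))
  cls <- x$classes
  cls$accuracy <- sprintf("%.2f%%", cls$accuracy_2dp)
  print.data.frame(cls[, c("class", "predicted", "n", "n_correct", "accuracy")],
                   row.names = FALSE)
  cat(sprintf("Overall accuracy: %.2f%%\n", x$overall_accuracy_2dp))
  invisible(x)
}

#' Compare prediction inaccuracy with marker-locus recombination
#'
#' Descriptive report pairing the percentage of incorrect phenotype
#' predictions (100 minus accuracy) with the summed genetic distance
#' between the markers and their trait loci: when markers are used as
#' proxies for loci, misprediction should be of the same order as the
#' recombination between marker and locus.
#'
#' @param accuracy Overall accuracy in percent, or an `assoc_table` (its
#'   truncated overall accuracy is used).
#' @param distances_cM Numeric vector of marker-to-locus distances in cM.
#' @return Object of class `assoc_rf_report`: `inaccuracy_pct`,
#'   `total_cM`, `distances_cM`.
#' @examples
#' accuracy_vs_recombination(82.60, c(9.8, 3.4))  # 17.40% vs 13.2 cM
#' @export
accuracy_vs_recombination <- function(accuracy, distances_cM) {
  if (inherits(accuracy, "assoc_table"))
    accuracy <- accuracy$overall_accuracy_2dp
  stopifnot(is.numeric(accuracy), length(accuracy) == 1,
            accuracy >= 0, accuracy <= 100, all(distances_cM >= 0))
  structure(list(inaccuracy_pct = round(100 - accuracy, 2),
                 total_cM = sum(distances_cM),
                 distances_cM = distances_cM),
            class = "assoc_rf_report")
}

#' @export
print.assoc_rf_report <- function(x, ...) {
  cat(sprintf("Inaccurate predictions: %.2f%%; total marker-locus distance: %.1f cM\n",
              x$inaccuracy_pct, x$total_cM))
  invisible(x)
}
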