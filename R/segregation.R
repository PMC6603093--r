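# Chi-square goodness-of-fit tests against Mendelian segregation ratios.

parse_ratio <- function(ratio) {
  if (inherits(ratio, "phenotype_ratio")) return(as.numeric(ratio$weights))
  if (is.character(ratio)) {
    stopifnot(length(ratio) == 1)
    ratio <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
  }
  if (anyNA(ratio) || any(ratio <= 0))
    stop("ratio weights must be positive numbers")
  as.numeric(ratio)
}

#' Chi-square goodness of fit against a Mendelian ratio
#'
#' Pearson's statistic `sum((O - E)^2 / E)` with expected counts
#' proportional to the ratio weights, tested on `classes - 1` degrees of
#' freedom. No continuity correction is applied (the classical segregation
#' chi-square).  A message is emitted when any expected count is below 5;
#' small recessive classes are common in F2 designs and the test is still
#' reported.
#'
#' @param observed Non-negative integer vector of phenotype counts
#'   (optionally named).
#' @param ratio Expected ratio: numeric weights, a string like `"12:3:1"`,
#'   or a `phenotype_ratio` from [expected_phenotype_ratio()].
#' @return Object of class `seg_test`: `observed`, `ratio`, `expected`,
#'   `statistic`, `df`, `p.value`.
#' @examples
#' chi_square_gof(c(88, 40), "3:1")        # chi2 = 2.67, p = 0.10
#' chi_square_gof(c(67, 22, 7), "12:3:1")  # chi2 = 1.40, p = 0.49
#' @export
chi_square_gof <- function(observed, ratio) {
  w <- parse_ratio(ratio)
  if (length(observed) < 2) stop("at least two phenotype classes are required")
  if (length(observed) != length(w))
    stop(sprintf("observed has %d classes but the ratio has %d",
                 length(observed), length(w)))
  if (any(observed < 0) || sum(observed) <= 0)
    stop("observed counts must be non-negative with positive total")
  ht <- suppressWarnings(chisq.test(observed, p = w / sum(w)))
  if (any(ht$expected < 5))
    message("note: expected count < 5 in at least one class")
  structure(list(observed = observed,
                 ratio = as.integer(w),
                 expected = as.numeric(ht$expected),
                 statistic = unname(ht$statistic),
                 df = as.integer(unname(ht$parameter)),
                 p.value = unname(ht$p.value)),
            class = "seg_test")
}

#' @export
print.seg_test <- function(x, digits = 2, ...) {
  lbl <- names(x$observed)
  cat(sprintf("Segregation test: observed (%s) vs ratio %s\n",
              paste(x$observed, collapse = ", "),
              paste(x$ratio, collapse = ":")))
  if (!is.null(lbl)) cat("  classes:", paste(lbl, collapse = ", "), "\n")
  cat(sprintf("  chi-square = %.*f, df = %d, p = %.*f\n",
              digits, round(x$statistic, digits), x$df,
              digits, x$p.value))
  invisible(x)
}

#' Rank candidate segregation ratios by goodness of fit
#'
#' Tests the observed counts against every candidate ratio and ranks the
#' candidates by descending p-value (ties broken by smaller chi-square), so
#' the best-supported Mendelian hypothesis comes first.
#'
#' @param observed Phenotype counts.
#' @param candidates List (optionally named) of ratios accepted by
#'   [chi_square_gof()]; candidates with a different number of classes are
#'   skipped with a message.
#' @return Object of class `ratio_selection`: a data frame `summary`
#'   (ratio, chi_square, df, p_value, rank) plus the full `tests`.
#' @examples
#' select_ratio(c(67, 22, 7), list("9:3:4", "12:3:1", "9:6:1"))
#' @export
select_ratio <- function(observed, candidates) {
  if (!is.list(candidates)) candidates <- as.list(candidates)
  labels <- names(candidates)
  if (is.null(labels)) labels <- rep("", length(candidates))
  tests <- list(); kept <- character(0)
  for (i in seq_along(candidates)) {
    w <- parse_ratio(candidates[[i]])
    lab <- if (nzchar(labels[i])) labels[i] else paste(w, collapse = ":")
    if (length(w) != length(observed)) {
      message("skipping candidate ", lab, ": class count mismatch")
      next
    }
    tests[[lab]] <- chi_square_gof(observed, w)
    kept <- c(kept, lab)
  }
  if (!length(tests)) stop("no candidate ratio is testable against these counts")
  s <- data.frame(ratio = kept,
                  chi_square = vapply(tests, `[[`, 0, "statistic"),
                  df = vapply(tests, function(t) as.integer(t$df), 0L),
                  p_value = vapply(tests, `[[`, 0, "p.value"),
                  stringsAsFactors = FALSE)
  s <- s[order(-s$p_value, s$chi_square), , drop = FALSE]
  s$rank <- seq_len(nrow(s))
  rownames(s) <- NULL
  structure(list(summary = s, tests = tests, observed = observed),
            class = "ratio_selection")
}

#' @export
print.ratio_selection <- function(x, ...) {
  cat("Candidate segregation ratios for observed (",
      paste(x$observed, collapse = ", "), "):\n", sep = "")
  s <- x$summary
  s$chi_square <- round(s$chi_square, 2)
  s$p_value <- signif(s$p_value, 3)
  print.data.frame(s, row.names = FALSE)
  invisible(x)
}

#' Segregation-distortion test for a codominant F2 marker
#'
#' Goodness of fit of AA/AB/BB genotype counts against the Mendelian 1:2:1
#' expectation, used as a marker quality filter (markers with
#' `p < alpha` are flagged as distorted).
#'
#' @param counts Length-3 vector of AA, AB, BB counts (zeros allowed).
#' @param alpha Significance level for the distortion flag (default
#'   0.0001, the conventional mapping QC cut-off).
#' @return A [chi_square_gof()] `seg_test` with an extra element
#'   `distorted` (logical) and `alpha`.
#' @export
distortion_test <- function(counts, alpha = 1e-4) {
  if (length(counts) != 3)
    stop("counts must be the three genotype classes AA, AB, BB")
  res <- chi_square_gof(counts, c(1, 2, 1))
  res$alpha <- alpha
  res$distorted <- res$p.value < alpha
  res
}
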