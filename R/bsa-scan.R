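# QTL-seq core: per-site SNP-index and delta SNP-index, site filtering,
# sliding-window averaging, simulation-based null thresholds, and QTL
# interval calling.

#' Per-site SNP-index for two bulks, with site filtering
#'
#' The SNP-index of a bulk at a position is the fraction of reads carrying
#' the alternate allele, `alt / (ref + alt)`.  Sites are dropped when
#' either bulk is below the minimum depth (including zero-depth bulks) or
#' when the SNP-index is below `min_index` in *both* bulks (such sites are
#' uninformative: the variant allele is essentially absent from both
#' pools).  A filter report is attached as an attribute.
#'
#' @param table A [bulk_depth_table()].
#' @param min_depth Minimum total depth required in each bulk (default 10).
#' @param min_index Sites with SNP-index below this in both bulks are
#'   dropped (default 0.3).
#' @return Data frame of class `snp_index_track`: `chrom`, `pos`,
#'   `index_a`, `index_b`, `depth_a`, `depth_b`; attributes `bulk_names`
#'   and `filter_report` (named counts of dropped sites).
#' @examples
#' tbl <- bulk_depth_table("chr1", c(100, 200), ref_a = c(40, 10),
#'                         alt_a = c(20, 10), ref_b = c(5, 10),
#'                         alt_b = c(55, 10))
#' compute_snp_index(tbl)
#' @export
compute_snp_index <- function(table, min_depth = 10, min_index = 0.3) {
  stopifnot(inherits(table, "bulk_depth_table"))
  depth_a <- table$ref_a + table$alt_a
  depth_b <- table$ref_b + table$alt_b
  idx_a <- ifelse(depth_a > 0, table$alt_a / depth_a, NA_real_)
  idx_b <- ifelse(depth_b > 0, table$alt_b / depth_b, NA_real_)
  zero_depth <- depth_a == 0 | depth_b == 0
  low_depth <- !zero_depth & (depth_a < min_depth | depth_b < min_depth)
  low_index <- !zero_depth & !low_depth &
    (idx_a < min_index & idx_b < min_index)
  keep <- !(zero_depth | low_depth | low_index)
  out <- data.frame(chrom = table$chrom[keep], pos = table$pos[keep],
                    index_a = idx_a[keep], index_b = idx_b[keep],
                    depth_a = depth_a[keep], depth_b = depth_b[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            bulk_names = attr(table, "bulk_names"),
            filter_report = c(input = nrow(table),
                              zero_depth = sum(zero_depth),
                              low_depth = sum(low_depth),
                              low_index_both = sum(low_index),
                              retained = sum(keep)),
            class = c("snp_index_track", "data.frame"))
}

#' Delta SNP-index with a declared subtraction order
#'
#' Adds the signed per-site difference of bulk SNP-indices, `delta =
#' index(first) - index(second)` for the declared bulk order (e.g. the
#' recessive bulk minus the dominant bulk), plus its absolute value.
#'
#' @param track A [compute_snp_index()] track.
#' @param order Length-2 character vector of bulk names (or indices 1:2)
#'   declaring the subtraction order; required, so the sign of every peak
#'   is interpretable.
#' @return The track with columns `delta` and `abs_delta` and attribute
#'   `delta_order`.
#' @export
delta_index <- function(track, order) {
  stopifnot(inherits(track, "snp_index_track"))
  bn <- attr(track, "bulk_names")
  if (missing(order) || length(order) != 2)
    stop("declare the subtraction order as c(first_bulk, second_bulk)")
  if (is.character(order)) {
    pos <- match(order, bn)
    if (anyNA(pos)) stop("unknown bulk name(s): ",
                         paste(order[is.na(pos)], collapse = ", "))
  } else pos <- as.integer(order)
  stopifnot(setequal(pos, 1:2))
  cols <- c("index_a", "index_b")[pos]
  track$delta <- track[[cols[1]]] - track[[cols[2]]]
  track$abs_delta <- abs(track$delta)
  attr(track, "delta_order") <- bn[pos]
  track
}

#' Sliding-window averages of the delta SNP-index
#'
#' Tiles each chromosome with half-open windows `[start, start + window)`
#' beginning at position 1 and advancing by `step_bp` (the classic QTL-seq
#' 1 Mb window with 10 kb step), and averages the per-site delta
#' SNP-index within each window.  Windows with fewer than `min_sites`
#' sites are kept in the output but flagged `retained = FALSE` and are
#' ignored by [call_qtl()].
#'
#' @param track A [delta_index()] track (must contain `delta`).
#' @param window_bp,step_bp Window and step size in bp; `window_bp` must be
#'   a multiple of, and at least, `step_bp`.
#' @param min_sites Minimum sites per retained window (default 10).
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   absent the last window is the one containing the last site.  End
#'   windows truncated by the chromosome end are retained if they still
#'   hold `min_sites` sites.
#' @return Data frame of class `bsa_windows`: `chrom`, `start`, `end`,
#'   `n_sites`, `mean_delta`, `mean_abs_delta`, `mean_depth`, `retained`.
#' @export
sliding_windows <- function(track, window_bp = 1e6, step_bp = 1e4,
                            min_sites = 10, chrom_lengths = NULL) {
  stopifnot(inherits(track, "snp_index_track"))
  if (is.null(track$delta)) stop("run delta_index() first")
  if (window_bp < step_bp) stop("window_bp must be >= step_bp")
  out <- lapply(unique(track$chrom), function(ch) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$pos), , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(tr$pos)
    starts <- seq(1, max(1, len), by = step_bp)
    if (!length(starts)) return(NULL)
    ends <- pmin(starts + window_bp - 1, len) + 1   # half-open end
    pos <- tr$pos
    cs_delta <- cumsum(tr$delta)
    cs_abs <- cumsum(abs(tr$delta))
    cs_depth <- cumsum((tr$depth_a + tr$depth_b) / 2)
    lo <- findInterval(starts - 1, pos) + 1         # first site >= start
    hi <- findInterval(ends - 1, pos)               # last site < end
    n <- pmax(hi - lo + 1, 0)
    sum_at <- function(cs, i) ifelse(i >= 1, cs[pmax(i, 1)], 0)
    sd_ <- sum_at(cs_delta, hi) - sum_at(cs_delta, lo - 1)
    sa_ <- sum_at(cs_abs, hi) - sum_at(cs_abs, lo - 1)
    sq_ <- sum_at(cs_depth, hi) - sum_at(cs_depth, lo - 1)
    data.frame(chrom = ch, start = starts, end = ends,
               n_sites = n,
               mean_delta = ifelse(n > 0, sd_ / n, NA_real_),
               mean_abs_delta = ifelse(n > 0, sa_ / n, NA_real_),
               mean_depth = ifelse(n > 0, sq_ / n, NA_real_),
               retained = n >= min_sites,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out,
            window_bp = window_bp, step_bp = step_bp, min_sites = min_sites,
            delta_order = attr(track, "delta_order"),
            class = c("bsa_windows", "data.frame"))
}

#' Simulation-based null thresholds for the delta SNP-index
#'
#' Simulates the no-QTL null distribution of the per-site delta SNP-index,
#' taking the population size, the number of individuals in each bulk, and
#' the read depth into account: each replicate draws an F2 population at an
#' unlinked biallelic locus (genotypes 1:2:1), samples the two bulks
#' without replacement, computes the true bulk allele frequencies, draws
#' alternate read counts `Binomial(depth, freq)` for each bulk, and forms
#' the delta SNP-index.  Per depth, the table records the symmetric
#' two-sided empirical quantile pair (`alpha/2` in each tail) and the
#' absolute calling threshold: the smallest observed `|delta|` whose
#' upper-tail probability is at most `alpha` (the critical-value
#' convention for a discrete null; a statistic is significant when it
#' *reaches* the threshold).  Between grid depths, thresholds are
#' linearly interpolated at query time by [threshold_at()].
#'
#' @param pop_size Number of F2 individuals in the population.
#' @param bulk_sizes Length-2 integer vector, individuals per bulk.
#' @param depths Numeric vector of read depths to simulate (the grid).
#' @param alphas Significance levels (default `c(0.05, 0.01)`).
#' @param replicates Null replicates per depth (default 10000; at least
#'   1000 recommended).
#' @param seed Optional integer seed.
#' @return Object of class `null_thresholds`: `table` (depth, alpha,
#'   lower, upper, abs_threshold) and the simulation parameters.
#' @export
simulate_null_thresholds <- function(pop_size, bulk_sizes, depths,
                                     alphas = c(0.05, 0.01),
                                     replicates = 10000, seed = NULL) {
  stopifnot(length(bulk_sizes) == 2, all(bulk_sizes >= 1),
            sum(bulk_sizes) <= pop_size, replicates >= 1,
            all(depths >= 1))
  depths <- round(depths)   # read counts are integral
  if (!is.null(seed)) set.seed(seed)
  delta <- simulate_null_delta(pop_size, bulk_sizes, depths, replicates)
  tab <- do.call(rbind, lapply(seq_along(depths), function(di) {
    d <- delta[, di]
    do.call(rbind, lapply(alphas, function(a) {
      q <- quantile(d, c(a / 2, 1 - a / 2), names = FALSE, type = 7)
      data.frame(depth = depths[di], alpha = a,
                 lower = q[1], upper = q[2],
                 abs_threshold = critical_value(abs(d), a))
    }))
  }))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 params = list(pop_size = pop_size, bulk_sizes = bulk_sizes,
                               depths = depths, alphas = alphas,
                               replicates = replicates, seed = seed)),
            class = "null_thresholds")
}

# Critical value for a discrete empirical null: the smallest observed
# value whose upper-tail probability (P(X >= x)) is at most alpha.
# Significance is attained when the statistic *reaches* this value, the
# standard convention for discrete test statistics; read counts make the
# per-site delta SNP-index discrete (atoms at multiples of 1/depth), so a
# plain quantile-plus-strict-exceedance rule would be systematically
# conservative.
critical_value <- function(x, alpha) {
  u <- sort(unique(x))
  n <- length(x)
  # P(X >= u) for each candidate, via the sorted sample
  tail_p <- 1 - (findInterval(u, sort(x), left.open = TRUE)) / n
  hit <- which(tail_p <= alpha)
  if (!length(hit)) Inf else u[hit[1]]
}

# Null delta SNP-index draws: replicates x length(depths) matrix.
simulate_null_delta <- function(pop_size, bulk_sizes, depths, replicates) {
  m1 <- bulk_sizes[1]; m2 <- bulk_sizes[2]
  q1 <- numeric(replicates); q2 <- numeric(replicates)
  for (i in seq_len(replicates)) {
    geno <- sample(c(0L, 1L, 2L), pop_size, replace = TRUE,
                   prob = c(0.25, 0.5, 0.25))
    idx <- sample.int(pop_size, m1 + m2)
    q1[i] <- sum(geno[idx[seq_len(m1)]]) / (2 * m1)
    q2[i] <- sum(geno[idx[m1 + seq_len(m2)]]) / (2 * m2)
  }
  vapply(depths, function(dp) {
    a1 <- rbinom(replicates, dp, q1) / dp
    a2 <- rbinom(replicates, dp, q2) / dp
    a1 - a2
  }, numeric(replicates))
}

#' Threshold lookup with depth interpolation
#'
#' @param thresholds A [simulate_null_thresholds()] object.
#' @param depth Numeric vector of depths (e.g. window mean depths).
#' @param alpha One of the simulated significance levels.
#' @return Absolute delta-SNP-index threshold(s) at the given depth(s),
#'   linearly interpolated across the simulated depth grid and clamped at
#'   its ends.
#' @export
threshold_at <- function(thresholds, depth, alpha) {
  stopifnot(inherits(thresholds, "null_thresholds"))
  tab <- thresholds$table[abs(thresholds$table$alpha - alpha) < 1e-12, ]
  if (!nrow(tab))
    stop(sprintf("no thresholds simulated for alpha = %g", alpha))
  if (nrow(tab) == 1) return(rep(tab$abs_threshold, length(depth)))
  approx(tab$depth, tab$abs_threshold, xout = depth, rule = 2)$y
}

#' @export
print.null_thresholds <- function(x, ...) {
  p <- x$params
  cat(sprintf("Null delta-SNP-index thresholds (pop %d, bulks %d/%d, %d replicates)\n",
              p$pop_size, p$bulk_sizes[1], p$bulk_sizes[2], p$replicates))
  print.data.frame(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Call QTL intervals from windowed delta SNP-index
#'
#' Retained windows whose `|mean_delta|` reaches the depth-interpolated
#' absolute threshold at the requested alpha are merged into maximal runs
#' of consecutive windows (same chromosome, starts one step apart).  Each
#' run becomes one interval spanning the union of its windows; the peak is
#' the window with the largest `|mean_delta|`.
#'
#' @param windows A [sliding_windows()] result.
#' @param thresholds A [simulate_null_thresholds()] object.
#' @param alpha Significance level (must be among the simulated alphas).
#' @return Data frame of class `qtl_intervals`: `chrom`, `start`, `end`
#'   (1-based, half-open), `peak_pos`, `peak_stat` (signed window mean at
#'   the peak), `n_windows`, `alpha`.
#' @export
call_qtl <- function(windows, thresholds, alpha = 0.01) {
  stopifnot(inherits(windows, "bsa_windows"))
  w <- windows[windows$retained & !is.na(windows$mean_delta), , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peak_pos = integer(0),
                      peak_stat = numeric(0), n_windows = integer(0),
                      alpha = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(w))
    return(structure(empty, class = c("qtl_intervals", "data.frame")))
  thr <- threshold_at(thresholds, w$mean_depth, alpha)
  # small tolerance so equal discrete atoms compare as ties regardless of
  # floating-point representation
  sig <- abs(w$mean_delta) >= thr - 1e-9
  w <- w[sig, , drop = FALSE]
  if (!nrow(w))
    return(structure(empty, class = c("qtl_intervals", "data.frame")))
  step <- attr(windows, "step_bp")
  newrun <- c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] |
                      diff(w$start) != step)
  run <- cumsum(newrun)
  out <- do.call(rbind, lapply(split(w, run), function(g) {
    peak <- g[which.max(abs(g$mean_delta)), ]
    data.frame(chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               peak_pos = as.integer(round((peak$start + peak$end) / 2)),
               peak_stat = peak$mean_delta,
               n_windows = nrow(g), alpha = alpha,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$chrom, unique(windows$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("qtl_intervals", "data.frame"))
}

#' @export
print.qtl_intervals <- function(x, ...) {
  if (!nrow(x)) {
    cat("No QTL intervals called.\n")
    return(invisible(x))
  }
  cat(sprintf("%d QTL interval(s):\n", nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s:%.2f-%.2f Mb, peak %.2f Mb, delta %.3f (p < %g)\n",
                x$chrom[i], x$start[i] / 1e6, x$end[i] / 1e6,
                x$peak_pos[i] / 1e6, x$peak_stat[i], x$alpha[i]))
  invisible(x)
}

#' Plot windowed delta SNP-index with significance thresholds
#'
#' One panel per chromosome: `|mean delta SNP-index|` of retained windows
#' against window midpoint, with the depth-interpolated threshold drawn as
#' a line.
#'
#' @param x A [sliding_windows()] result.
#' @param thresholds Optional [simulate_null_thresholds()] object.
#' @param alpha Significance level for the threshold line.
#' @param ... Passed to [plot()].
#' @export
plot.bsa_windows <- function(x, thresholds = NULL, alpha = 0.01, ...) {
  chroms <- unique(x$chrom)
  op <- par(mfrow = c(length(chroms), 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (ch in chroms) {
    w <- x[x$chrom == ch & x$retained, , drop = FALSE]
    mid <- (w$start + w$end) / 2
    plot(mid / 1e6, abs(w$mean_delta), type = "l",
         xlab = "position (Mb)", ylab = "|delta SNP-index|",
         main = ch, ylim = c(0, 1), ...)
    if (!is.null(thresholds))
      lines(mid / 1e6, threshold_at(thresholds, w$mean_depth, alpha),
            col = "red", lty = 2)
  }
  invisible(x)
}
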