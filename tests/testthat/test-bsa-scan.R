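# helper: track with given per-site deltas, built through the public API
delta_track <- function(pos, delta, chrom = "chr1", depth = 80,
                        order = c("b2", "b1")) {
  # choose depths so that index_b - index_a equals the requested delta:
  # bulk a index 0.5 everywhere, bulk b index 0.5 + delta
  ref_b <- round(depth * (1 - (0.5 + delta / 2)))
  alt_b <- depth - ref_b
  ref_a <- round(depth * (1 - (0.5 - delta / 2)))
  alt_a <- depth - ref_a
  tbl <- bulk_depth_table(chrom, pos, ref_a, alt_a, ref_b, alt_b,
                          bulk_names = c("b1", "b2"))
  delta_index(compute_snp_index(tbl, min_depth = 1, min_index = 0),
              order = order)
}

test_that("SNP-index and delta follow the read-count arithmetic", {
  tbl <- bulk_depth_table("chr1", c(100, 200, 300),
                          ref_a = c(10, 0, 40), alt_a = c(10, 20, 20),
                          ref_b = c(10, 0, 5), alt_b = c(10, 20, 55),
                          bulk_names = c("D-bulk", "G-bulk"))
  tr <- compute_snp_index(tbl)
  expect_equal(tr$index_a, c(0.5, 1, 1 / 3))
  expect_equal(tr$index_b, c(0.5, 1, 11 / 12))
  tr <- delta_index(tr, order = c("G-bulk", "D-bulk"))
  expect_equal(tr$delta[3], 11 / 12 - 1 / 3)     # 0.5833
  expect_equal(tr$delta[1], 0)
  # swapping the order negates delta
  tr2 <- delta_index(compute_snp_index(tbl), order = c("D-bulk", "G-bulk"))
  expect_equal(tr2$delta, -tr$delta)
  expect_error(delta_index(compute_snp_index(tbl)), "order")
  expect_error(delta_index(tr, order = c("X", "D-bulk")), "unknown")
})

test_that("site filters drop zero-depth, low-depth and uninformative sites", {
  tbl <- bulk_depth_table("chr1", 1:5 * 100,
                          ref_a = c(20, 0, 4, 30, 20), alt_a = c(20, 0, 4, 2, 20),
                          ref_b = c(20, 10, 20, 30, 12), alt_b = c(20, 10, 20, 2, 0))
  tr <- compute_snp_index(tbl)
  fr <- attr(tr, "filter_report")
  expect_equal(unname(fr["zero_depth"]), 1)      # site 2: bulk a empty
  expect_equal(unname(fr["low_depth"]), 1)       # site 3: depth 8 < 10
  expect_equal(unname(fr["low_index_both"]), 1)  # site 4: 1/16 in both
  expect_equal(unname(fr["retained"]), 2)        # sites 1 and 5
  expect_equal(tr$pos, c(100, 500))
  # site 5 kept: index 0.5 in bulk a even though bulk b is 0
  expect_true(all(tr$index_a >= 0 & tr$index_a <= 1))
  expect_true(all(tr$index_b >= 0 & tr$index_b <= 1))
})

test_that("bounds hold after filtering for arbitrary depth tables", {
  set.seed(21)
  for (i in 1:20) {
    n <- 50
    tbl <- bulk_depth_table("c", sort(sample.int(1e6, n)),
                            rpois(n, 30), rpois(n, 30),
                            rpois(n, 30), rpois(n, 30))
    tr <- delta_index(compute_snp_index(tbl), order = 1:2)
    expect_true(all(tr$index_a >= 0 & tr$index_a <= 1))
    expect_true(all(tr$delta >= -1 & tr$delta <= 1))
  }
})

test_that("sliding windows tile, average and count sites correctly", {
  # uniform delta: every window mean equals it
  tr <- delta_track(seq(5000, 3e6, by = 1e4), 0.4)
  w <- sliding_windows(tr, window_bp = 1e6, step_bp = 1e4, min_sites = 10)
  expect_true(all(abs(w$mean_delta[w$retained] - 0.4) < 1e-9))
  expect_equal(unique(diff(w$start[w$chrom == "chr1"])), 1e4)

  # a single site at 1.5 Mb falls in exactly 100 windows (1 Mb / 10 kb)
  tr1 <- delta_track(1500000, 0.4)
  w1 <- sliding_windows(tr1, 1e6, 1e4, min_sites = 1)
  expect_equal(sum(w1$n_sites > 0), 100)

  # window means are invariant to site order within a window
  tr_perm <- tr
  set.seed(4)
  tr_perm[] <- tr_perm[sample(nrow(tr_perm)), ]
  w_perm <- sliding_windows(tr_perm, 1e6, 1e4, min_sites = 10)
  expect_equal(w_perm$mean_delta, w$mean_delta)

  # chromosome shorter than the window: truncated windows, retained when
  # they hold enough sites
  tr_short <- delta_track(seq(5000, 3e5, by = 1e4), 0.2)
  w_short <- sliding_windows(tr_short, 1e6, 1e4, min_sites = 10,
                             chrom_lengths = c(chr1 = 3e5))
  expect_true(all(w_short$end <= 3e5 + 1))
  expect_true(any(w_short$retained))
  expect_error(sliding_windows(tr, window_bp = 1e3, step_bp = 1e4), "window")
})

test_that("null thresholds are depth-discrete at depth 1 and widen as information shrinks", {
  set.seed(31)
  d1 <- seedqtl:::simulate_null_delta(128, c(18, 18), depths = 1,
                                      replicates = 500)
  expect_true(all(d1 %in% c(-1, 0, 1)))

  thr <- simulate_null_thresholds(128, c(18, 18), depths = c(20, 200),
                                  replicates = 4000, seed = 32)
  t20 <- threshold_at(thr, 20, 0.05)
  t200 <- threshold_at(thr, 200, 0.05)
  expect_gt(t20, t200)      # lower depth -> wider threshold
  # interpolation lies between the grid values and clamps outside
  t110 <- threshold_at(thr, 110, 0.05)
  expect_true(t110 <= t20 && t110 >= t200)
  expect_equal(threshold_at(thr, 5, 0.05), t20)
  expect_equal(threshold_at(thr, 1e4, 0.05), t200)
  # 1% thresholds are wider than 5%
  expect_gt(threshold_at(thr, 20, 0.01), t20)
  expect_error(threshold_at(thr, 20, 0.10), "alpha")

  thr_small <- simulate_null_thresholds(128, c(7, 7), depths = 200,
                                        replicates = 4000, seed = 33)
  expect_gt(threshold_at(thr_small, 200, 0.05), t200)  # smaller bulks -> wider
  expect_error(simulate_null_thresholds(10, c(8, 8), depths = 80), "bulk")
})

test_that("null threshold exceedance is near its nominal level", {
  thr <- simulate_null_thresholds(128, c(18, 18), depths = 80,
                                  replicates = 6000, seed = 41)
  set.seed(42)
  fresh <- seedqtl:::simulate_null_delta(128, c(18, 18), depths = 80,
                                         replicates = 6000)
  rate <- mean(abs(fresh) >= threshold_at(thr, 80, 0.05) - 1e-9)
  expect_lt(abs(rate - 0.05), 0.015)
})

test_that("interval calling merges consecutive significant windows", {
  thr <- flat_thresholds(0.3, alpha = 0.01)
  # flat null track: nothing called
  tr0 <- delta_track(seq(5000, 5e6, by = 1e4), 0.0)
  w0 <- sliding_windows(tr0, 1e6, 1e4)
  expect_equal(nrow(call_qtl(w0, thr, 0.01)), 0)

  # one elevated block on each of two chromosomes
  pos <- seq(5000, 1e7, by = 1e4)
  mk_delta <- function(center) ifelse(abs(pos - center) < 1.2e6, 0.6, 0)
  tr <- rbind(delta_track(pos, mk_delta(5e6), chrom = "chr1"),
              delta_track(pos, mk_delta(3e6), chrom = "chr2"))
  class(tr) <- c("snp_index_track", "data.frame")
  attr(tr, "delta_order") <- c("b2", "b1")
  w <- sliding_windows(tr, 1e6, 1e4)
  qtl <- call_qtl(w, thr, 0.01)
  expect_equal(nrow(qtl), 2)
  expect_equal(qtl$chrom, c("chr1", "chr2"))
  # each causal center lies inside its interval
  expect_true(qtl$start[1] <= 5e6 && 5e6 < qtl$end[1])
  expect_true(qtl$start[2] <= 3e6 && 3e6 < qtl$end[2])
  # peak statistic carries the (positive) sign of the injected signal
  expect_true(all(qtl$peak_stat > 0.3))
})
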