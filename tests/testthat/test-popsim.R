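test_that("single-marker genotype frequencies are Mendelian (1:2:1)", {
  map <- genetic_map(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = 5e5, name = "m1"))
  pop <- simulate_f2(map, 10000, seed = 7)
  freq <- tabulate(pop$geno[, 1] + 1L, nbins = 3) / 10000
  expect_equal(freq, c(0.25, 0.5, 0.25), tolerance = 0.05)
  # and a formal check: no segregation distortion at this n
  expect_false(distortion_test(tabulate(pop$geno[, 1] + 1L, 3))$distorted)
})

test_that("tightly linked markers co-segregate; 10 cM markers recombine at the inverse-Kosambi rate", {
  # adjacent positions: inter-marker distance 1 bp ~ 3e-6 cM
  map <- genetic_map(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = c(100, 101),
                                name = c("m1", "m2")))
  pop <- simulate_f2(map, 500, seed = 11)
  expect_identical(pop$geno[, 1], pop$geno[, 2])

  # 10 cM apart: recombination fraction (e^{0.4}-1)/(2(e^{0.4}+1)) = 0.0987,
  # evaluated here independently of the package's map functions
  r_true <- (exp(4 * 10 / 100) - 1) / (2 * (exp(4 * 10 / 100) + 1))
  map10 <- genetic_map(c(chr1 = 1e7),
                       data.frame(chrom = "chr1", pos = c(1e6, 1e6 + 10 * 3e5),
                                  name = c("m1", "m2")), bp_per_cM = 3e5)
  pop10 <- simulate_f2(map10, 50000, seed = 11)
  codes <- c("a", "h", "b")
  r_hat <- estimate_rf(codes[pop10$geno[, 1] + 1L],
                       codes[pop10$geno[, 2] + 1L])$r
  expect_equal(r_hat, r_true, tolerance = 0.05)
  expect_equal(r_true, 0.0987, tolerance = 1e-3)
})

test_that("chromosomes assort independently and seeds reproduce exactly", {
  map <- genetic_map(c(chr1 = 1e6, chr2 = 1e6),
                     data.frame(chrom = c("chr1", "chr2"), pos = c(5e5, 5e5),
                                name = c("m1", "m2")))
  pop1 <- simulate_f2(map, 2000, seed = 3)
  pop2 <- simulate_f2(map, 2000, seed = 3)
  expect_identical(pop1$geno, pop2$geno)
  # independence across chromosomes: correlation near zero
  expect_lt(abs(cor(pop1$geno[, 1], pop1$geno[, 2])), 0.08)
})

test_that("phenotype assignment reproduces expected class fractions", {
  map <- genetic_map(c(chr1 = 1e6, chr2 = 1e6),
                     data.frame(chrom = c("chr1", "chr2"), pos = c(5e5, 5e5),
                                name = c("mR", "mT")))
  # single-locus 3:1 over many seeds at the study's n = 128
  set.seed(100)
  frac <- replicate(60, {
    pop <- simulate_f2(map, 128)
    pop <- assign_phenotypes(pop, single_model(), c(R = "mR"))
    mean(pop$phenotype == "dotted black")
  })
  expect_equal(mean(frac), 0.75, tolerance = 0.015)

  # 12:3:1 fractions at n = 96
  set.seed(101)
  fr <- rowMeans(replicate(60, {
    pop <- simulate_f2(map, 96)
    pop <- assign_phenotypes(pop, rt1_model(), c(R = "mR", T1 = "mT"))
    c(mean(pop$phenotype == "dotted black"),
      mean(pop$phenotype == "tan1"),
      mean(pop$phenotype == "red"))
  }))
  expect_equal(fr, c(12, 3, 1) / 16, tolerance = 0.03)

  # all-AA population: a single phenotype class
  allAA <- manual_pop(matrix(0L, 10, 2, dimnames = list(NULL, c("mR", "mT"))),
                      map)
  allAA <- assign_phenotypes(allAA, rt1_model(), c(R = "mR", T1 = "mT"))
  expect_equal(unique(allAA$phenotype), "dotted black")
})

test_that("bulk selection respects phenotype, size and determinism", {
  map <- genetic_map(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = 5e5, name = "mR"))
  pop <- simulate_f2(map, 128, seed = 5)
  pop <- assign_phenotypes(pop, single_model(), c(R = "mR"))
  specs <- list(bulk_spec("D-bulk", "dotted black", 18),
                bulk_spec("G-bulk", "green", 18))
  b1 <- make_bulks(pop, specs, seed = 9)
  b2 <- make_bulks(pop, specs, seed = 9)
  expect_identical(b1, b2)
  expect_equal(lengths(b1), c("D-bulk" = 18L, "G-bulk" = 18L))
  expect_true(all(pop$phenotype[b1$`G-bulk`] == "green"))
  expect_false(anyDuplicated(b1$`D-bulk`) > 0)
  # size equal to the eligible count selects everyone
  n_green <- sum(pop$phenotype == "green")
  all_green <- make_bulks(pop, bulk_spec("G-bulk", "green", n_green), seed = 1)
  expect_equal(all_green$`G-bulk`, which(pop$phenotype == "green"))
  # too large a request errors, naming the bulk
  expect_error(make_bulks(pop, bulk_spec("R-bulk", "green", 1000)), "R-bulk")
})

test_that("bulk depth sampling matches genotype-frequency arithmetic", {
  map <- genetic_map(c(chr1 = 2e6),
                     data.frame(chrom = "chr1",
                                pos = seq(1e4, 2e6, by = 1e4),
                                name = paste0("m", 1:200)))
  # all-BB bulk with zero error: SNP-index exactly 1 at every site
  popBB <- manual_pop(matrix(2L, 30, 200,
                             dimnames = list(NULL, paste0("m", 1:200))), map)
  tbl <- sample_bulk_depths(popBB, list(b1 = 1:15, b2 = 16:30),
                            mean_depth = 80, error_rate = 0, seed = 2)
  expect_true(all(tbl$ref_a == 0) && all(tbl$ref_b == 0))

  # all-heterozygous bulk: q = 0.5, mean SNP-index ~ 0.5 across sites
  popAB <- manual_pop(matrix(1L, 30, 200,
                             dimnames = list(NULL, paste0("m", 1:200))), map)
  tbl2 <- sample_bulk_depths(popAB, list(b1 = 1:15, b2 = 16:30),
                             mean_depth = 80, error_rate = 0, seed = 2)
  expect_equal(mean(tbl2$alt_a / (tbl2$ref_a + tbl2$alt_a)), 0.5,
               tolerance = 0.02)

  # same seed gives a bit-identical table
  expect_identical(sample_bulk_depths(popAB, list(b1 = 1:15, b2 = 16:30),
                                      mean_depth = 80, seed = 4),
                   sample_bulk_depths(popAB, list(b1 = 1:15, b2 = 16:30),
                                      mean_depth = 80, seed = 4))
  expect_error(sample_bulk_depths(popAB, list(b1 = integer(0), b2 = 1:5)),
               "empty")
})

test_that("dominant-carrier bulks converge to SNP-index 1/3 at the causal locus", {
  # among dominant carriers the genotypes are 1 AA : 2 AB, so the
  # recessive-parent allele frequency is exactly 1/3 in expectation
  map <- genetic_map(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = 5e5, name = "mR"))
  set.seed(12)
  idx <- replicate(300, {
    pop <- simulate_f2(map, 128)
    pop <- assign_phenotypes(pop, single_model(), c(R = "mR"))
    b <- make_bulks(pop, list(bulk_spec("D", "dotted black", 18),
                              bulk_spec("G", "green", 10)))
    tbl <- sample_bulk_depths(pop, b, mean_depth = 500, error_rate = 0)
    tbl$alt_a / (tbl$ref_a + tbl$alt_a)
  })
  # absolute band ~4.5x the Monte-Carlo standard error of the mean
  expect_lt(abs(mean(idx) - 1 / 3), 0.015)
})

test_that("map validation catches unordered and out-of-range markers", {
  expect_error(genetic_map(c(chr1 = 1e6),
                           data.frame(chrom = "chr1", pos = c(200, 200),
                                      name = c("a", "b"))), "increasing")
  expect_error(genetic_map(c(chr1 = 1e3),
                           data.frame(chrom = "chr1", pos = 2e3, name = "a")),
               "outside")
  expect_error(genetic_map(c(chr1 = 1e6),
                           data.frame(chrom = "chr2", pos = 10, name = "a")),
               "unknown")
  map <- genetic_map(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = 10, name = "a"))
  expect_error(simulate_f2(map, 0), "positive")
})
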