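test_that("size factors follow the median-of-ratios definition", {
  # identical columns -> all factors 1
  m <- matrix(rep(c(2L, 5L, 9L), 3), ncol = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), rep(1, 3))

  # doubling a column doubles its factor relative to the other
  m2 <- cbind(a = c(2L, 4L, 8L), b = c(4L, 8L, 16L))
  rownames(m2) <- paste0("g", 1:3)
  f <- size_factors(m2)
  expect_equal(unname(f["b"] / f["a"]), 2)

  # hand-computed median-of-ratios on the worked 3x2 example
  m3 <- cbind(a = c(2L, 4L, 8L), b = c(4L, 16L, 16L))
  rownames(m3) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m3)), c(sqrt(0.5), sqrt(2)),
               tolerance = 1e-12)

  # no all-positive reference gene -> informative error
  m4 <- cbind(a = c(0L, 5L), b = c(5L, 0L))
  rownames(m4) <- paste0("g", 1:2)
  expect_error(size_factors(m4), "filter")
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  counts <- toy_two_group_counts(n_genes = 300, n = 5, mu = 80, fc_b = 1.5,
                                 seed = 3)
  ours <- size_factors(counts)
  ref <- suppressMessages(DESeq2::estimateSizeFactorsForMatrix(counts))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-5)
})

test_that("normalization divides by factors and round-trips exactly", {
  counts <- toy_two_group_counts(n_genes = 20, n = 3, seed = 2)
  f <- size_factors(counts)
  norm <- normalize_counts(counts, f)
  expect_equal(sweep(norm, 2, f, "*"), counts + 0, tolerance = 1e-14)
  expect_equal(normalize_counts(counts, rep(1, ncol(counts))), counts + 0)
  half <- normalize_counts(counts, c(2, rep(1, ncol(counts) - 1)))
  expect_equal(half[, 1], counts[, 1] / 2)
  expect_error(normalize_counts(counts, rep(-1, ncol(counts))), "positive")
})

test_that("dispersion estimates are negligible for Poisson data and floored for constants", {
  set.seed(11)
  n <- 50
  counts <- matrix(rpois(1000 * n, 500), nrow = 1000,
                   dimnames = list(sprintf("g%04d", 1:1000),
                                   sprintf("s%02d", 1:n)))
  groups <- rep(c("a", "b"), each = n / 2)
  alpha <- estimate_dispersion(counts, rep(1, n), groups)
  expect_gt(mean(alpha < 1e-3), 0.95)

  const <- matrix(7L, nrow = 2, ncol = 4,
                  dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  a2 <- estimate_dispersion(const, rep(1, 4), rep("a", 4))
  expect_equal(unname(a2), rep(1e-8, 2))
})

test_that("dispersion recovery at alpha 0.2, mu 500, n 50 per group", {
  set.seed(21)
  n_rep <- 200  # each gene is an independent replicate of the experiment
  counts <- matrix(rnbinom(n_rep * 100, mu = 500, size = 1 / 0.2),
                   nrow = n_rep,
                   dimnames = list(sprintf("g%04d", 1:n_rep),
                                   sprintf("s%03d", 1:100)))
  groups <- rep(c("a", "b"), each = 50)
  alpha <- estimate_dispersion(counts, rep(1, 100), groups)
  expect_gt(median(alpha), 0.1)
  expect_lt(median(alpha), 0.3)
})

test_that("Wald test is antisymmetric in group order and flags all-zero genes", {
  counts <- toy_two_group_counts(n_genes = 60, n = 4, mu = 150, fc_b = 2,
                                 seed = 5)
  counts[1, ] <- 0L
  f <- rep(1, ncol(counts))
  names(f) <- colnames(counts)
  groups <- rep(c("a", "b"), each = 4)
  disp <- estimate_dispersion(counts, f, groups)
  ab <- nb_wald_test(counts, f, disp, colnames(counts)[1:4],
                     colnames(counts)[5:8])
  ba <- nb_wald_test(counts, f, disp, colnames(counts)[5:8],
                     colnames(counts)[1:4])
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-12)
  expect_equal(ab$flag[1], "all_zero")
  expect_equal(ab$pvalue[1], 1)
  expect_equal(ab$log2fc[1], 0)
  expect_true(all(ab$padj >= ab$pvalue))
})

test_that("planted log2 fold change of 2 is recovered near-unbiasedly", {
  set.seed(31)
  n_rep <- 200
  a <- matrix(rnbinom(n_rep * 6, mu = 200, size = 1 / 0.05), nrow = n_rep)
  b <- matrix(rnbinom(n_rep * 6, mu = 800, size = 1 / 0.05), nrow = n_rep)
  counts <- cbind(a, b)
  dimnames(counts) <- list(sprintf("g%04d", 1:n_rep), sprintf("s%02d", 1:12))
  f <- setNames(rep(1, 12), colnames(counts))
  disp <- estimate_dispersion(counts, f, rep(c("a", "b"), each = 6))
  de <- nb_wald_test(counts, f, disp, colnames(counts)[1:6],
                     colnames(counts)[7:12])
  expect_lt(abs(median(de$log2fc) - 2), 0.3)
})

test_that("multiplying one sample's column rescales only its relative size factor", {
  counts <- toy_two_group_counts(n_genes = 120, n = 4, mu = 200, seed = 7)
  f1 <- size_factors(counts)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 3L
  f2 <- size_factors(scaled)
  # factors are defined relative to the geometric-mean pseudo-reference,
  # so the exact statement is about factor ratios: the scaled sample gains
  # exactly 3x relative to every untouched sample, whose mutual ratios are
  # unchanged
  expect_equal(unname((f2[2] / f2[1]) / (f1[2] / f1[1])), 3,
               tolerance = 1e-12)
  expect_equal(unname(f2[-2] / f2[3]), unname(f1[-2] / f1[3]),
               tolerance = 1e-12)
  groups <- rep(c("a", "b"), each = 4)
  d1 <- estimate_dispersion(counts, f1, groups)
  d2 <- estimate_dispersion(scaled, f2, groups)
  de1 <- nb_wald_test(counts, f1, d1, colnames(counts)[1:4],
                      colnames(counts)[5:8])
  de2 <- nb_wald_test(scaled, f2, d2, colnames(counts)[1:4],
                      colnames(counts)[5:8])
  # downstream results shift only through the common pseudo-reference
  # rescaling (3^(1/8) here) interacting with the pseudocount, a
  # sub-milli-unit effect on fold changes
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 1e-3)
  expect_gt(cor(de1$stat, de2$stat), 0.999)
})

test_that("BH adjustment matches the textbook step-up exactly", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(41)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))
    expect_equal(adjust_bh(p), bh_stepup_bruteforce(p), tolerance = 1e-14)
  }
})

test_that("DEG calls use strict fold-change and p thresholds", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(1.2, 1.0, -3, 0.5),
                   pvalue = c(1e-6, 1e-9, 1e-7, 1e-9),
                   padj = c(1e-4, 1e-6, 1e-4, 1e-6))
  # raw-p volcano criterion keeps |lfc| > 1 and p < 1e-5
  expect_equal(call_degs(de, fc_threshold = 2, p_threshold = 1e-5,
                         use_adjusted = FALSE), c("a", "c"))
  # boundary |log2fc| = 1 is excluded under strict inequality
  expect_false("b" %in% call_degs(de, 2, 1e-5, use_adjusted = FALSE))
  expect_equal(call_degs(de[0, ], 2, 1e-5), character())
  expect_error(call_degs(de, fc_threshold = -1, p_threshold = 0.05),
               "positive")
})
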