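ranked_fixture <- function(n, seed = 1) {
  set.seed(seed)
  stats <- sort(rnorm(n), decreasing = TRUE)
  names(stats) <- sprintf("g%03d", sample(n))
  stats
}

test_that("gene ranking is descending by fold change with lexicographic ties", {
  de <- data.frame(gene = c("gm", "gp"), log2fc = c(-1, 1))
  expect_equal(names(rank_genes(de)), c("gp", "gm"))
  de2 <- data.frame(gene = c("b", "a", "c"), log2fc = c(0, 0, 0))
  expect_equal(names(rank_genes(de2)), c("a", "b", "c"))
  # input order never matters
  de3 <- data.frame(gene = c("c", "a", "b"), log2fc = c(0.5, 0.5, 2))
  expect_identical(rank_genes(de3), rank_genes(de3[3:1, ]))
  expect_error(rank_genes(data.frame(gene = "a", log2fc = NA_real_)),
               "complete")
})

test_that("enrichment score hits the running-sum extremes for single-member sets", {
  stats <- ranked_fixture(20)
  top <- preranked_es(stats, names(stats)[1])
  expect_equal(top$es, 1)
  expect_equal(top$argmax, 1L)
  expect_equal(top$leading_edge, names(stats)[1])
  bottom <- preranked_es(stats, names(stats)[20])
  expect_equal(bottom$es, -1)
  expect_error(preranked_es(stats, names(stats)), "universe")
  expect_error(preranked_es(stats, "absent"), "no member")
})

test_that("enrichment score equals brute-force enumeration on random cases", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    stats <- ranked_fixture(n, seed = 1000 + i)
    set <- sample(names(stats), sample(2:min(10, n - 1), 1))
    expect_equal(preranked_es(stats, set)$es, es_bruteforce(stats, set),
                 tolerance = 1e-14)
  }
})

test_that("enrichment score matches the reference preranked implementation", {
  for (i in 1:20) {
    stats <- ranked_fixture(60, seed = 200 + i)
    set <- sample(names(stats), 8)
    ref <- suppressWarnings(
      fgsea::calcGseaStat(stats, which(names(stats) %in% set),
                          gseaParam = 1))
    expect_equal(preranked_es(stats, set)$es, ref, tolerance = 1e-12)
  }
})

test_that("negating and reversing the ranking negates the score", {
  for (i in 1:20) {
    stats <- ranked_fixture(40, seed = 300 + i)
    set <- sample(names(stats), 6)
    flipped <- rev(-stats)
    expect_equal(preranked_es(flipped, set)$es, -preranked_es(stats, set)$es,
                 tolerance = 1e-12)
  }
})

test_that("permutation p-values are calibrated, deterministic and never zero", {
  stats <- ranked_fixture(400, seed = 9)
  coll <- lapply(1:60, function(i) sample(names(stats), 20))
  names(coll) <- sprintf("set%02d", 1:60)
  res <- preranked_test(stats, coll, nperm = 200, seed = 5)
  expect_true(all(res$pvalue >= 1 / 201))
  expect_lte(mean(res$padj < 0.05), 0.07)
  res2 <- preranked_test(stats, coll, nperm = 200, seed = 5)
  expect_identical(res$pvalue, res2$pvalue)
  # planted set in the top decile reaches the permutation floor
  planted <- list(planted = names(stats)[1:15])
  res3 <- preranked_test(stats, planted, nperm = 999, seed = 2)
  expect_equal(res3$pvalue, 1 / 1000)
  expect_equal(res3$direction, "enriched")
  expect_error(preranked_test(stats, coll, nperm = 10), "at least 100")
})

test_that("sets outside size bounds are skipped", {
  stats <- ranked_fixture(100, seed = 4)
  coll <- list(tiny = names(stats)[1:2], ok = names(stats)[1:10])
  expect_message(res <- preranked_test(stats, coll, nperm = 100, seed = 1,
                                       min_size = 5),
                 "skipping")
  expect_equal(res$set, "ok")
})

test_that("per-sample scores depend only on within-sample ranks", {
  set.seed(13)
  mat <- matrix(rexp(200 * 4), nrow = 200,
                dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  coll <- list(a = rownames(mat)[1:20], b = rownames(mat)[51:90])
  sc <- per_sample_scores(mat, coll)
  # strictly monotone transform of one sample leaves its scores unchanged
  mat2 <- mat
  mat2[, 2] <- exp(mat2[, 2] / 3)
  expect_equal(per_sample_scores(mat2, coll)[2, ], sc[2, ], tolerance = 1e-12)
  # identical samples get identical rows
  mat3 <- cbind(mat, s5 = mat[, 1])
  sc3 <- per_sample_scores(mat3, coll)
  expect_equal(sc3[1, ], sc3[5, ], tolerance = 1e-12)
  # scores bounded in [-1, 1]
  expect_true(all(abs(sc) <= 1))
})

test_that("a sample's own top genes maximize its score for that set", {
  set.seed(14)
  mat <- matrix(rnorm(300 * 5), nrow = 300,
                dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:5)))
  top_s3 <- rownames(mat)[order(-mat[, 3])][1:25]
  sc <- per_sample_scores(mat, list(top = top_s3))
  expect_equal(unname(which.max(sc[, "top"])), 3L)
})

test_that("differential enrichment calls separation with the right direction", {
  set.seed(15)
  sc <- matrix(rnorm(12 * 30, sd = 0.02), nrow = 12,
               dimnames = list(sprintf("s%02d", 1:12), sprintf("set%02d", 1:30)))
  groups <- setNames(rep(c("young", "old"), each = 6), rownames(sc))
  # null: no calls on exchangeable scores
  null_res <- differential_enrichment(sc, groups, "young", "old")
  expect_equal(sum(null_res$called), 0L)
  # planted: a large constant shift with tiny variance is called
  sc[7:12, 1] <- sc[7:12, 1] + 0.8
  res <- differential_enrichment(sc, groups, "young", "old")
  expect_true(res$called[1])
  expect_equal(res$direction[1], "enriched")
  # swapping group labels flips direction and preserves p
  swapped <- differential_enrichment(sc, groups, "old", "young")
  expect_equal(swapped$diff, -res$diff, tolerance = 1e-12)
  expect_equal(swapped$pvalue, res$pvalue, tolerance = 1e-12)
  expect_error(differential_enrichment(sc[1:3, ],
                                       setNames(c("a", "a", "b"),
                                                rownames(sc)[1:3]),
                                       "a", "b"),
               "at least 2")
})

test_that("over-representation p equals the exact hypergeometric and enumeration", {
  universe <- paste0("g", 1:10)
  set <- universe[1:5]
  hits <- universe[c(1:4)]
  res <- overrepresentation_test(hits, universe, list(s = set))
  expect_equal(res$pvalue, 5 / 210, tolerance = 1e-12)
  expect_equal(res$fraction, 4 / 5)
  # exhaustive enumeration oracle on small universes
  set.seed(16)
  for (i in 1:15) {
    n <- sample(6:12, 1)
    uni <- paste0("g", seq_len(n))
    s <- sample(uni, sample(2:(n - 1), 1))
    lst <- sample(uni, sample(1:(n - 2), 1))
    res_i <- overrepresentation_test(lst, uni, list(s = s))
    expect_equal(res_i$pvalue, hypergeom_enumerate(lst, s, uni),
                 tolerance = 1e-12)
  }
  # zero overlap when zero is the minimum possible -> p = 1
  res0 <- overrepresentation_test("g9", universe, list(s = universe[1:3]))
  expect_equal(res0$pvalue, 1)
  expect_warning(res_e <- overrepresentation_test(character(), universe,
                                                  list(s = set)),
                 "empty")
  expect_equal(res_e$pvalue, 1)
})
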