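#' Rank genes by fold change
#'
#' Sorts a DE table descending by log2 fold change (older group over
#' younger); ties are broken by gene id, lexicographically, so the ranking
#' is deterministic.
#'
#' @param de a `de_result` data frame.
#' @return named numeric vector of log2 fold changes, sorted descending.
#' @export
rank_genes <- function(de) {
  if (is.null(de$log2fc) || any(is.na(de$log2fc)))
    stop("DE table must carry complete log2 fold changes")
  ord <- order(-de$log2fc, de$gene)
  stats::setNames(de$log2fc[ord], de$gene[ord])
}

#' Weighted running-sum enrichment score
#'
#' Classic pre-ranked enrichment score: walking down the ranked list, set
#' members ("hits") increment the running sum by `|stat|^weight` normalized
#' by the total hit weight, non-members decrement by `1 / (N - N_set)`; the
#' score is the running-sum value of largest absolute magnitude. The
#' leading edge comprises the set members at or before the extremum
#' (positive score) or at or after it (negative score).
#'
#' @param stats named statistic vector, already ranked (see
#'   [rank_genes()]).
#' @param set character vector of member gene ids.
#' @param weight exponent on `|stat|` for hit increments (default 1; 0
#'   gives the unweighted Kolmogorov-Smirnov-like score).
#' @return list with `es`, `argmax` (1-based position of the extremum) and
#'   `leading_edge` (gene ids).
#' @export
preranked_es <- function(stats, set, weight = 1) {
  n <- length(stats)
  hit <- names(stats) %in% set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("set has no member in the ranked universe")
  if (n_hit == n) stop("set equals the universe; miss denominator is zero")
  w <- abs(stats)^weight
  inc <- rep(-1 / (n - n_hit), n)
  total <- sum(w[hit])
  # all-zero hit weights (e.g. flat statistics at weight 1): fall back to
  # equal hit increments so the running sum remains well defined
  inc[hit] <- if (total > 0) w[hit] / total else 1 / n_hit
  run <- cumsum(inc)
  argmax <- which.max(abs(run))
  es <- run[argmax]
  le <- if (es >= 0) which(hit & seq_len(n) <= argmax)
        else which(hit & seq_len(n) >= argmax)
  list(es = es, argmax = argmax, leading_edge = names(stats)[le])
}

#' Pre-ranked gene-set enrichment with permutation p-values
#'
#' Computes the running-sum enrichment score for each set and a
#' permutation null by drawing random same-size gene sets (gene-label
#' sampling without replacement). P-values are sign-consistent:
#' `p = (1 + #{null of matching sign with |ES_null| >= |ES|}) / (nperm + 1)`.
#' The normalized score divides ES by the mean `|ES_null|` of matching
#' sign. BH adjustment is applied across the retained sets.
#'
#' @param stats ranked statistic vector (see [rank_genes()]).
#' @param collection named list of gene-id vectors.
#' @param nperm permutations per set size (>= 100).
#' @param seed RNG seed for the permutation draws.
#' @param min_size,max_size set-size bounds after intersection with the
#'   universe; sets outside are skipped with a log message.
#' @param weight passed to [preranked_es()].
#' @return data frame: set, size, es, nes, pvalue, padj, direction
#'   (`enriched`/`depleted` at the top of the ranking), leading_edge
#'   (comma-separated).
#' @export
preranked_test <- function(stats, collection, nperm = 1000L, seed = 1L,
                           min_size = 5L, max_size = 500L, weight = 1) {
  if (nperm < 100L) stop("`nperm` must be at least 100")
  universe <- names(stats)
  trimmed <- lapply(collection, intersect, y = universe)
  sizes <- lengths(trimmed)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep))
    message("INFO: skipping ", sum(!keep),
            " set(s) outside size bounds [", min_size, ", ", max_size, "]")
  trimmed <- trimmed[keep]
  sizes <- sizes[keep]
  if (!length(trimmed))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), pvalue = numeric(), padj = numeric(),
                      direction = character(), leading_edge = character(),
                      stringsAsFactors = FALSE))

  es_obs <- lapply(trimmed, function(s) preranked_es(stats, s, weight))
  null_by_size <- with_seed(seed, {
    out <- list()
    for (sz in sort(unique(sizes))) {
      out[[as.character(sz)]] <- vapply(seq_len(nperm), function(i) {
        preranked_es(stats, sample(universe, sz), weight)$es
      }, numeric(1L))
    }
    out
  })

  res <- lapply(names(trimmed), function(nm) {
    es <- es_obs[[nm]]$es
    null <- null_by_size[[as.character(length(trimmed[[nm]]))]]
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    p <- (1 + sum(abs(same) >= abs(es))) / (nperm + 1)
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = length(trimmed[[nm]]), es = es, nes = nes,
               pvalue = p,
               direction = if (es >= 0) "enriched" else "depleted",
               leading_edge = paste(es_obs[[nm]]$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- adjust_bh(res$pvalue)
  res[, c("set", "size", "es", "nes", "pvalue", "padj", "direction",
          "leading_edge")]
}

#' Per-sample gene-set enrichment scores
#'
#' For each sample, genes are ranked by expression (descending; ties broken
#' by gene id) and each set is scored by the normalized integral of the
#' hit-minus-miss running sum along the ranking: hits increment by their
#' normalized rank weight (`|N - rank + 1|^weight`; equal increments at the
#' default `weight = 0`), misses decrement by `1 / (N - N_set)`, and the
#' score is `sum(running sum) / ((N + 1) / 2)`. At `weight = 0` this equals
#' the scaled difference between the mean rank position of non-members and
#' members, so the score responds linearly to a coherent rank shift of the
#' set, is symmetric for up- and down-shifts, lies in `[-1, 1]`, and
#' depends only on within-sample ranks.
#'
#' @param mat transformed expression matrix, genes x samples.
#' @param collection named list of gene-id vectors.
#' @param min_size,max_size set-size bounds after universe intersection.
#' @param weight exponent on the rank statistic (default 0, unweighted).
#' @return samples x sets numeric matrix.
#' @export
per_sample_scores <- function(mat, collection, min_size = 5L, max_size = 500L,
                              weight = 0) {
  universe <- rownames(mat)
  trimmed <- lapply(collection, intersect, y = universe)
  sizes <- lengths(trimmed)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep))
    message("INFO: skipping ", sum(!keep),
            " set(s) outside size bounds [", min_size, ", ", max_size, "]")
  trimmed <- trimmed[keep]
  if (!length(trimmed)) stop("no set left after size filtering")
  n <- nrow(mat)
  scores <- matrix(NA_real_, nrow = ncol(mat), ncol = length(trimmed),
                   dimnames = list(colnames(mat), names(trimmed)))
  for (s in seq_len(ncol(mat))) {
    ord <- order(-mat[, s], universe)
    ranked <- stats::setNames(as.numeric(n:1), universe[ord])
    for (k in seq_along(trimmed))
      scores[s, k] <- running_sum_integral(ranked, trimmed[[k]], weight)
  }
  scores
}

# normalized integral of the hit/miss running sum; bounded in [-1, 1]
running_sum_integral <- function(stats, set, weight = 0) {
  n <- length(stats)
  hit <- names(stats) %in% set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("set has no member in the ranked universe")
  if (n_hit == n) stop("set equals the universe; miss denominator is zero")
  w <- abs(stats)^weight
  inc <- rep(-1 / (n - n_hit), n)
  total <- sum(w[hit])
  inc[hit] <- if (total > 0) w[hit] / total else 1 / n_hit
  sum(cumsum(inc)) / ((n + 1) / 2)
}

#' Differential gene-set enrichment between two sample groups
#'
#' Per set, a two-sample unequal-variance (Welch) test on the per-sample
#' scores between the groups, BH-adjusted across sets. The enrichment
#' difference is the difference of group mean scores (group B minus group
#' A); calls require `padj < fdr_threshold` and
#' `|difference| > diff_threshold`.
#'
#' @param scores samples x sets matrix from [per_sample_scores()].
#' @param groups group label per sample (named by sample or aligned to
#'   rows).
#' @param group_a,group_b the two group labels (A = reference).
#' @param fdr_threshold BH-adjusted p threshold (default 1e-5).
#' @param diff_threshold enrichment-difference threshold (default 0.5).
#' @return data frame: set, mean_a, mean_b, diff, stat, pvalue, padj,
#'   called, direction (`enriched`/`depleted` in group B).
#' @export
differential_enrichment <- function(scores, groups, group_a, group_b,
                                    fdr_threshold = 1e-5,
                                    diff_threshold = 0.5) {
  if (!is.null(names(groups))) groups <- groups[rownames(scores)]
  if (length(groups) != nrow(scores))
    stop("need one group label per score row")
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both groups need at least 2 samples")
  res <- lapply(colnames(scores), function(nm) {
    xa <- scores[ia, nm]
    xb <- scores[ib, nm]
    dmean <- mean(xb) - mean(xa)
    tt <- tryCatch(stats::t.test(xb, xa, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {  # essentially constant data
      p <- if (dmean == 0) 1 else .Machine$double.xmin
      stat <- if (dmean == 0) 0 else sign(dmean) * Inf
    } else {
      p <- tt$p.value
      stat <- unname(tt$statistic)
    }
    data.frame(set = nm, mean_a = mean(xa), mean_b = mean(xb), diff = dmean,
               stat = stat, pvalue = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- adjust_bh(res$pvalue)
  res$called <- res$padj < fdr_threshold & abs(res$diff) > diff_threshold
  res$direction <- ifelse(res$diff > 0, "enriched", "depleted")
  res
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric p-value on the overlap of a gene
#' list with each set, BH-adjusted across sets; also reports the
#' overlap-over-set-size fraction.
#'
#' @param genes character vector of hit genes (subset of `universe`).
#' @param universe character vector of all analyzed genes.
#' @param collection named list of gene-id vectors.
#' @return data frame: set, set_size, overlap, fraction, pvalue, padj.
#' @export
overrepresentation_test <- function(genes, universe, collection) {
  if (anyDuplicated(universe)) stop("universe ids must be unique")
  genes <- unique(genes)
  if (!all(genes %in% universe))
    stop("gene list must be a subset of the universe")
  if (length(genes) == 0L)
    warning("empty gene list; all p-values are 1")
  res <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    ov <- length(intersect(genes, set))
    p <- if (length(genes) == 0L) 1 else
      stats::phyper(ov - 1L, length(set), length(universe) - length(set),
                    length(genes), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = ov,
               fraction = if (length(set)) ov / length(set) else NA_real_,
               pvalue = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- adjust_bh(res$pvalue)
  res
}
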