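#' Median-of-ratios size factors
#'
#' Computes per-sample library-size factors as the median, over reference
#' genes, of each sample's counts divided by the gene's geometric mean
#' across samples. Reference genes are those with strictly positive counts
#' in every sample. Factors are not rescaled further.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has strictly positive counts in every sample; ",
         "filter low-count genes or supply factors from another reference")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(exp(logc - loggeo), 2L, stats::median)
}

#' Normalize counts by size factors
#'
#' @param counts genes x samples matrix.
#' @param factors positive factors, one per sample.
#' @return matrix of `counts[, s] / factors[s]`.
#' @export
normalize_counts <- function(counts, factors) {
  if (length(factors) != ncol(counts))
    stop("need one size factor per sample")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("size factors must be positive and finite")
  sweep(counts, 2L, factors, "/")
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene estimate `alpha = max((v - mu) / mu^2, floor)` where `mu` is the
#' mean of normalized counts and `v` the within-group variance pooled across
#' the supplied groups. No trend or shrinkage is applied.
#'
#' @param counts genes x samples count matrix.
#' @param factors size factors (see [size_factors()]).
#' @param groups group label per sample (character or factor).
#' @param floor lower bound on the estimate.
#' @return named numeric vector of dispersions, one per gene.
#' @export
estimate_dispersion <- function(counts, factors, groups, floor = 1e-8) {
  if (length(groups) != ncol(counts))
    stop("need one group label per sample")
  norm <- normalize_counts(counts, factors)
  groups <- as.character(groups)
  tab <- table(groups)
  if (!any(tab >= 2L))
    stop("dispersion estimation needs at least one group with >= 2 replicates")
  used <- names(tab)[tab >= 2L]
  ss <- 0
  df <- 0L
  for (g in used) {
    cols <- which(groups == g)
    gm <- rowMeans(norm[, cols, drop = FALSE])
    ss <- ss + rowSums((norm[, cols, drop = FALSE] - gm)^2)
    df <- df + length(cols) - 1L
  }
  v <- ss / df
  mu <- rowMeans(norm)
  alpha <- rep(floor, nrow(counts))
  pos <- mu > 0
  alpha[pos] <- pmax((v[pos] - mu[pos]) / mu[pos]^2, floor)
  if (any(!pos))
    message("INFO: ", sum(!pos), " all-zero gene(s) given floor dispersion")
  stats::setNames(alpha, rownames(counts))
}

#' Negative-binomial Wald test between two sample groups
#'
#' Group means are fitted per gene as the mean of size-factor-normalized
#' counts within each group (each observation inversely weighted by its
#' size factor), so the fit is invariant to rescaling any one sample's
#' library. The reported log2 fold change is the ratio of pseudocounted
#' (+0.5) normalized group means, group B over group A. The standard error
#' comes from the NB variance at the fitted means, the Wald statistic is
#' `log2FC / SE`, and two-sided p-values use the standard normal
#' reference; BH-adjusted p-values are appended.
#'
#' @param counts genes x samples count matrix.
#' @param factors size factors, named by sample.
#' @param dispersion per-gene NB dispersion (see [estimate_dispersion()]).
#' @param samples_a,samples_b column ids of the two groups (A = reference,
#'   typically the younger age; B = the older age).
#' @param pseudocount added to normalized group means before the ratio.
#' @return data frame of class `de_result`: gene, base_mean, log2fc, se,
#'   stat, pvalue, padj, flag ("ok" or "all_zero").
#' @export
nb_wald_test <- function(counts, factors, dispersion, samples_a, samples_b,
                         pseudocount = 0.5) {
  if (length(samples_a) < 2L || length(samples_b) < 2L)
    stop("both groups need at least 2 samples")
  missing <- setdiff(c(samples_a, samples_b), colnames(counts))
  if (length(missing))
    stop("samples not in count matrix: ", paste(missing, collapse = ", "))
  if (is.null(names(factors))) names(factors) <- colnames(counts)
  alpha <- dispersion[rownames(counts)]
  if (any(is.na(alpha))) stop("dispersion missing for some genes")

  ka <- counts[, samples_a, drop = FALSE]
  kb <- counts[, samples_b, drop = FALSE]
  sa <- factors[samples_a]
  sb <- factors[samples_b]
  na <- length(samples_a)
  nb <- length(samples_b)
  qa <- rowMeans(sweep(ka, 2L, sa, "/"))
  qb <- rowMeans(sweep(kb, 2L, sb, "/"))
  mua <- qa + pseudocount
  mub <- qb + pseudocount
  log2fc <- log2(mub / mua)
  # q is the mean of normalized counts; Var(k_s) = s_s mu + alpha (s_s mu)^2
  # gives Var(q) = mu sum(1/s) / n^2 + alpha mu^2 / n, hence
  # Var(log2 q) = (sum(1/s) / (n^2 mu) + alpha / n) / ln(2)^2
  vla <- (sum(1 / sa) / (na^2 * mua) + alpha / na) / log(2)^2
  vlb <- (sum(1 / sb) / (nb^2 * mub) + alpha / nb) / log(2)^2
  se <- sqrt(vla + vlb)
  stat <- log2fc / se
  pvalue <- 2 * stats::pnorm(-abs(stat))

  zero <- rowSums(ka) + rowSums(kb) == 0
  log2fc[zero] <- 0
  stat[zero] <- 0
  pvalue[zero] <- 1

  norm <- normalize_counts(counts[, c(samples_a, samples_b), drop = FALSE],
                           factors[c(samples_a, samples_b)])
  out <- data.frame(gene = rownames(counts),
                    base_mean = rowMeans(norm),
                    log2fc = log2fc, se = se, stat = stat, pvalue = pvalue,
                    padj = adjust_bh(pvalue),
                    flag = ifelse(zero, "all_zero", "ok"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", class(out))
  out
}

#' Differential expression for one age contrast
#'
#' Convenience wrapper: size factors and pooled dispersion are estimated on
#' the full matrix across all age groups, then [nb_wald_test()] is run on
#' the two requested ages. The contrast is named `"<B>m_vs_<A>m"` with B the
#' older age.
#'
#' @param counts genes x samples count matrix.
#' @param metadata data frame with columns `sample` and `age_months`.
#' @param age_a,age_b ages (months) of the reference and test group.
#' @param factors,dispersion optionally precomputed; estimated if `NULL`.
#' @return a `de_result` data frame with attribute `contrast`.
#' @export
de_contrast <- function(counts, metadata, age_a, age_b,
                        factors = NULL, dispersion = NULL) {
  if (!all(c("sample", "age_months") %in% names(metadata)))
    stop("metadata needs columns `sample` and `age_months`")
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(
      counts, factors, metadata$age_months[match(colnames(counts), metadata$sample)])
  sa <- metadata$sample[metadata$age_months == age_a]
  sb <- metadata$sample[metadata$age_months == age_b]
  if (!length(sa) || !length(sb))
    stop("no samples at age ", if (!length(sa)) age_a else age_b, " months")
  de <- nb_wald_test(counts, factors, dispersion, sa, sb)
  attr(de, "contrast") <- sprintf("%gm_vs_%gm", age_b, age_a)
  de
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()] after
#' validating the input).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Strict thresholds on fold change and (raw or adjusted) p-value:
#' `|log2FC| > log2(fc_threshold)` and `p < p_threshold`.
#'
#' @param de a `de_result` data frame.
#' @param fc_threshold fold-change threshold (default 2).
#' @param p_threshold p-value threshold.
#' @param use_adjusted use `padj` (default) rather than raw `pvalue`.
#' @return character vector of gene ids.
#' @export
call_degs <- function(de, fc_threshold = 2, p_threshold = 0.001,
                      use_adjusted = TRUE) {
  if (fc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be positive")
  if (nrow(de) == 0L) return(character())
  p <- if (use_adjusted) de$padj else de$pvalue
  de$gene[abs(de$log2fc) > log2(fc_threshold) & p < p_threshold]
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || ncol(counts) < 2L)
    stop("counts must be a matrix with at least 2 samples")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("gene and sample ids must be unique")
  invisible(TRUE)
}
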