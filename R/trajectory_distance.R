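#' Log transform of normalized counts
#'
#' `log2(x + 1)` applied elementwise, a monotone variance-flattening
#' transform for normalized counts used ahead of distance and PCA
#' computations.
#'
#' @param x non-negative matrix of normalized counts.
#' @return transformed matrix, same dimensions.
#' @export
log_transform <- function(x) {
  if (any(x < 0)) stop("normalized counts must be non-negative")
  log2(x + 1)
}

#' Per-group mean expression profiles
#'
#' @param mat transformed matrix, genes x samples.
#' @param metadata data frame with `sample` and `age_months`.
#' @return matrix genes x groups, columns named `"<age>m"` and ordered by
#'   age.
#' @export
group_mean_profiles <- function(mat, metadata) {
  ages <- sort(unique(metadata$age_months))
  profiles <- vapply(ages, function(a) {
    cols <- metadata$sample[metadata$age_months == a]
    if (!length(cols)) stop("empty group at age ", a)
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  colnames(profiles) <- paste0(ages, "m")
  attr(profiles, "ages") <- ages
  profiles
}

#' Euclidean distance between group mean profiles
#'
#' `D[a, b] = sqrt(sum_g (mean_a,g - mean_b,g)^2)` over the full gene
#' universe of the supplied profiles.
#'
#' @param profiles genes x groups matrix (see [group_mean_profiles()]).
#' @return symmetric distance matrix with zero diagonal; the `ages`
#'   attribute of `profiles` is carried along.
#' @export
pairwise_group_distance <- function(profiles) {
  if (ncol(profiles) < 2L) stop("need at least two group profiles")
  d <- as.matrix(stats::dist(t(profiles), method = "euclidean"))
  attr(d, "ages") <- attr(profiles, "ages")
  d
}

#' Per-month divergence rates along consecutive age intervals
#'
#' Divides the transcriptomic distance between consecutive age groups by
#' the age difference in months, and reports the ratio of the last
#' interval's rate over the preceding interval's.
#'
#' @param d distance matrix from [pairwise_group_distance()].
#' @param ages ages in months aligned to the rows/columns of `d`; taken
#'   from the `ages` attribute when omitted.
#' @return list with `rates` (data frame: from, to, months, distance, rate)
#'   and `rate_ratio` (last over preceding interval; `NA` with fewer than
#'   two intervals).
#' @export
divergence_rates <- function(d, ages = attr(d, "ages")) {
  if (is.null(ages)) stop("ages not supplied and not attached to `d`")
  if (anyDuplicated(ages)) stop("duplicate ages")
  ord <- order(ages)
  ages <- ages[ord]
  d <- d[ord, ord, drop = FALSE]
  k <- length(ages) - 1L
  rates <- data.frame(
    from = ages[seq_len(k)], to = ages[seq_len(k) + 1L],
    months = diff(ages),
    distance = d[cbind(seq_len(k), seq_len(k) + 1L)])
  rates$rate <- rates$distance / rates$months
  ratio <- if (k >= 2L) rates$rate[k] / rates$rate[k - 1L] else NA_real_
  list(rates = rates, rate_ratio = ratio)
}

#' Rank age groups by distance to a reference group
#'
#' Sorts the non-reference groups by their transcriptomic distance to the
#' reference, ascending; exact ties are broken by age, youngest first. The
#' first entry is the "nearest" group — on an aging trajectory where the
#' oldest group re-approaches the youngest, the oldest group ranks first.
#'
#' @param d distance matrix from [pairwise_group_distance()].
#' @param reference row/column name of the reference group (e.g. `"2m"`).
#' @return list with `ranking` (data frame: group, age, distance) and
#'   `nearest` (group label).
#' @export
reversion_index <- function(d, reference) {
  if (!reference %in% rownames(d))
    stop("unknown reference group: ", reference)
  ages <- attr(d, "ages")
  if (is.null(ages)) ages <- as.numeric(sub("m$", "", rownames(d)))
  others <- setdiff(rownames(d), reference)
  dist_ref <- d[reference, others]
  age_others <- ages[match(others, rownames(d))]
  ord <- order(dist_ref, age_others)
  ranking <- data.frame(group = others[ord], age = age_others[ord],
                        distance = unname(dist_ref[ord]),
                        stringsAsFactors = FALSE)
  list(ranking = ranking, nearest = ranking$group[1L])
}

#' Within-group mean pairwise sample distance
#'
#' Mean Euclidean distance over all within-group sample pairs; groups with
#' a single sample are reported as `NA`.
#'
#' @param mat transformed matrix, genes x samples.
#' @param metadata data frame with `sample` and `age_months`.
#' @return named numeric vector, one value per age group (`"<age>m"`).
#' @export
within_group_variance <- function(mat, metadata) {
  ages <- sort(unique(metadata$age_months))
  out <- vapply(ages, function(a) {
    cols <- metadata$sample[metadata$age_months == a]
    if (length(cols) < 2L) return(NA_real_)
    mean(stats::dist(t(mat[, cols, drop = FALSE])))
  }, numeric(1L))
  stats::setNames(out, paste0(ages, "m"))
}

#' Principal components of the top-variance genes
#'
#' Restricts to the `ntop` genes with the highest variance across samples
#' (all genes if fewer), centers per gene without scaling, and
#' eigendecomposes the sample covariance. Component signs are fixed so that
#' each loading vector's largest-magnitude entry is positive.
#'
#' @param mat transformed matrix, genes x samples.
#' @param ntop number of top-variance genes (default 5000).
#' @return list with `scores` (samples x components), `var_frac`
#'   (per-component variance fractions) and `loadings`.
#' @export
pca_scores <- function(mat, ntop = 5000L) {
  if (ntop < 2L) stop("`ntop` must be at least 2")
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  v <- apply(mat, 1L, stats::var)
  keep <- utils::head(order(v, decreasing = TRUE), min(ntop, nrow(mat)))
  pc <- stats::prcomp(t(mat[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(w) {
    sign(w[which.max(abs(w))])
  })
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, "*")
  loadings <- sweep(pc$rotation, 2L, flip, "*")
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, var_frac = var_frac, loadings = loadings)
}
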