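#' Relative quantification by the delta-delta-Ct method
#'
#' Replicate Ct values are averaged per (sample, target); then
#' `dCt = Ct_target - Ct_reference` per sample,
#' `ddCt = dCt - mean(dCt over calibrator samples)`, and the relative
#' quantity is `2^(-ddCt)` (amplification efficiency 2 assumed). Centering
#' the calibrator on its arithmetic-mean dCt makes the calibrator group's
#' geometric-mean quantity exactly 1.
#'
#' @param table qPCR data frame: sample, age_months, target, replicate, ct.
#' @param target target label to quantify.
#' @param reference reference target label (e.g. a housekeeping gene).
#' @param calibrator_group age (months) of the calibrator group.
#' @return data frame: sample, age_months, dct, ddct, quantity.
#' @export
delta_delta_ct <- function(table, target, reference, calibrator_group) {
  ct <- average_replicates(table)
  wide <- merge(ct[ct$target == target, c("sample", "age_months", "ct")],
                ct[ct$target == reference, c("sample", "ct")],
                by = "sample", suffixes = c("_target", "_reference"),
                all.x = TRUE)
  drop <- is.na(wide$ct_reference)
  if (any(drop)) {
    warning("WARN [QPCR_MISSING_REF] dropping ", sum(drop),
            " sample(s) without reference Ct")
    wide <- wide[!drop, ]
  }
  if (!any(wide$age_months == calibrator_group))
    stop("calibrator group ", calibrator_group, " not present")
  wide$dct <- wide$ct_target - wide$ct_reference
  wide$ddct <- wide$dct - mean(wide$dct[wide$age_months == calibrator_group])
  wide$quantity <- 2^(-wide$ddct)
  wide[order(wide$age_months, wide$sample),
       c("sample", "age_months", "dct", "ddct", "quantity")]
}

#' Mitochondrial-to-nuclear DNA copy ratio
#'
#' `ratio = 2^(Ct_nuclear - Ct_mito)` per sample (replicates averaged
#' first), without a per-diploid-genome correction, plus per-age-group
#' mean and standard deviation.
#'
#' @param table qPCR data frame with targets `mito` and `nuclear`.
#' @return list with `samples` (sample, age_months, dct, ratio) and
#'   `groups` (age_months, mean_ratio, sd_ratio, n).
#' @export
mito_copy_ratio <- function(table) {
  ct <- average_replicates(table)
  wide <- merge(ct[ct$target == "mito", c("sample", "age_months", "ct")],
                ct[ct$target == "nuclear", c("sample", "ct")],
                by = "sample", suffixes = c("_mito", "_nuclear"), all = TRUE)
  drop <- is.na(wide$ct_mito) | is.na(wide$ct_nuclear)
  if (any(drop)) {
    warning("WARN [QPCR_MISSING_TARGET] dropping ", sum(drop),
            " sample(s) missing a target")
    wide <- wide[!drop, ]
  }
  wide$dct <- wide$ct_nuclear - wide$ct_mito
  wide$ratio <- 2^wide$dct
  samples <- wide[order(wide$age_months, wide$sample),
                  c("sample", "age_months", "dct", "ratio")]
  rownames(samples) <- NULL
  ages <- sort(unique(samples$age_months))
  groups <- data.frame(
    age_months = ages,
    mean_ratio = vapply(ages, function(a)
      mean(samples$ratio[samples$age_months == a]), numeric(1L)),
    sd_ratio = vapply(ages, function(a)
      stats::sd(samples$ratio[samples$age_months == a]), numeric(1L)),
    n = vapply(ages, function(a)
      sum(samples$age_months == a), integer(1L)))
  list(samples = samples, groups = groups)
}

#' Correlate copy-number trajectory with gene-set mean expression
#'
#' Pearson correlation, across age groups, between the per-group mean copy
#' ratio and the per-group mean of the set's mean transformed expression.
#'
#' @param copy result of [mito_copy_ratio()].
#' @param mat transformed expression matrix, genes x samples.
#' @param metadata data frame with `sample` and `age_months`.
#' @param set character vector of gene ids.
#' @return list with `r` (Pearson correlation), `n_groups`, and the paired
#'   per-group values.
#' @export
correlate_with_set_mean <- function(copy, mat, metadata, set) {
  set <- intersect(set, rownames(mat))
  if (!length(set)) stop("set has no member in the expression matrix")
  ages <- intersect(copy$groups$age_months, unique(metadata$age_months))
  if (length(ages) < 3L)
    stop("need at least 3 matched age groups for a stable correlation")
  set_mean <- vapply(ages, function(a) {
    cols <- metadata$sample[metadata$age_months == a]
    mean(colMeans(mat[set, cols, drop = FALSE]))
  }, numeric(1L))
  ratio <- copy$groups$mean_ratio[match(ages, copy$groups$age_months)]
  list(r = stats::cor(ratio, set_mean, method = "pearson"),
       n_groups = length(ages),
       values = data.frame(age_months = ages, mean_ratio = ratio,
                           set_mean_expression = set_mean))
}

# replicate-averaged Ct per (sample, target), carrying age_months along
average_replicates <- function(table) {
  need <- c("sample", "age_months", "target", "ct")
  if (!all(need %in% names(table)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(table$ct)) || any(table$ct <= 0) || any(table$ct >= 45))
    stop("Ct values must be positive cycles below 45")
  agg <- stats::aggregate(ct ~ sample + age_months + target, data = table,
                          FUN = mean)
  agg
}
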