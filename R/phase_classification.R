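#' Classify genes into aging-phase categories
#'
#' Applies the two-interval rule on the early (E: 24m vs 2m) and late
#' (L: 28m vs 24m) contrasts: a gene is `E` if significantly changed in the
#' E interval only (`padj_E < sig_alpha` and `padj_L > nonsig_alpha`), `L`
#' symmetrically, `EL` if significant in both, and `none` otherwise —
#' including the grey zone `sig_alpha <= padj <= nonsig_alpha` in the other
#' interval, which the rule leaves unclassified by construction.
#'
#' @param de_e,de_l `de_result` tables for the early and late contrast,
#'   covering the same gene universe.
#' @param sig_alpha adjusted-p significance threshold (default 0.001).
#' @param nonsig_alpha adjusted-p non-significance threshold (default 0.1).
#' @return data frame of class `phase_labels`: gene, phase, el_subtype
#'   (filled by [subtype_el()]; `not_applicable` here), padj_e, padj_l,
#'   lfc_e, lfc_l.
#' @export
classify_phases <- function(de_e, de_l, sig_alpha = 0.001, nonsig_alpha = 0.1) {
  if (!(sig_alpha > 0 && sig_alpha < nonsig_alpha && nonsig_alpha <= 1))
    stop("need 0 < sig_alpha < nonsig_alpha <= 1")
  if (!setequal(de_e$gene, de_l$gene) || anyDuplicated(de_e$gene)) {
    diff <- union(setdiff(de_e$gene, de_l$gene), setdiff(de_l$gene, de_e$gene))
    stop("DE tables must cover the same gene universe; symmetric difference: ",
         paste(utils::head(diff, 10L), collapse = ", "),
         if (length(diff) > 10L) ", ..." else "")
  }
  de_l <- de_l[match(de_e$gene, de_l$gene), ]
  sig_e <- de_e$padj < sig_alpha
  sig_l <- de_l$padj < sig_alpha
  ns_e <- de_e$padj > nonsig_alpha
  ns_l <- de_l$padj > nonsig_alpha
  phase <- rep("none", nrow(de_e))
  phase[sig_e & ns_l] <- "E"
  phase[sig_l & ns_e] <- "L"
  phase[sig_e & sig_l] <- "EL"
  out <- data.frame(gene = de_e$gene, phase = phase,
                    el_subtype = "not_applicable",
                    padj_e = de_e$padj, padj_l = de_l$padj,
                    lfc_e = de_e$log2fc, lfc_l = de_l$log2fc,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("phase_labels", class(out))
  out
}

#' Subtype EL-aging genes by trajectory shape
#'
#' EL genes are split by the signs of their interval fold changes:
#' up-then-down (`downturn`), down-then-up (`upturn`), or continuously
#' rising/falling (`continuous_up` / `continuous_down`). A zero fold change
#' on an EL gene is flagged `indeterminate` and excluded from subtype
#' counts.
#'
#' @param labels output of [classify_phases()].
#' @return the labels with `el_subtype` filled in for EL genes.
#' @export
subtype_el <- function(labels) {
  el <- labels$phase == "EL"
  st <- rep("not_applicable", nrow(labels))
  up_e <- labels$lfc_e > 0
  up_l <- labels$lfc_l > 0
  zero <- labels$lfc_e == 0 | labels$lfc_l == 0
  st[el & up_e & !up_l] <- "downturn"
  st[el & !up_e & up_l] <- "upturn"
  st[el & up_e & up_l] <- "continuous_up"
  st[el & !up_e & !up_l] <- "continuous_down"
  if (any(el & zero)) {
    st[el & zero] <- "indeterminate"
    message("INFO: ", sum(el & zero),
            " EL gene(s) with zero fold change flagged indeterminate")
  }
  labels$el_subtype <- st
  labels
}

#' Summarize phase-classification labels
#'
#' @param labels output of [classify_phases()] / [subtype_el()].
#' @return list with `counts` (per phase), `subtype_counts` (per EL
#'   subtype), `fractions` (counts / universe) and `universe` size.
#' @export
class_summary <- function(labels) {
  phases <- c("E", "L", "EL", "none")
  counts <- stats::setNames(
    vapply(phases, function(p) sum(labels$phase == p), integer(1L)), phases)
  subtypes <- c("downturn", "upturn", "continuous_up", "continuous_down",
                "indeterminate")
  sub_counts <- stats::setNames(
    vapply(subtypes, function(s) sum(labels$el_subtype == s), integer(1L)),
    subtypes)
  n <- nrow(labels)
  list(counts = counts, subtype_counts = sub_counts,
       fractions = counts / n, universe = n)
}
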