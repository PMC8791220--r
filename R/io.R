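#' Read a gene x sample count matrix from TSV
#'
#' First column = gene id, header = sample ids. Counts must be
#' non-negative integers; duplicate gene or sample ids and negative or
#' non-integer values are hard errors naming the offending entry.
#'
#' @param path TSV file path.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("count matrix needs a gene column and >= 2 samples")
  gene <- as.character(df[[1L]])
  if (anyDuplicated(gene))
    stop("duplicate gene id at row ", which(duplicated(gene))[1L])
  if (anyDuplicated(colnames(df)[-1L]))
    stop("duplicate sample id: ",
         colnames(df)[-1L][duplicated(colnames(df)[-1L])][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("counts must be numeric")
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid count at gene ", gene[bad[1L, 1L]], ", sample ",
         colnames(m)[bad[1L, 2L]])
  storage.mode(m) <- "integer"
  rownames(m) <- gene
  m
}

#' Write a count matrix to TSV
#' @param counts genes x samples matrix.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample`, `age_months`, `tissue`; a `group` column is
#' derived from the age when absent.
#'
#' @param path TSV file path.
#' @param counts optional count matrix to validate against (every column
#'   must have exactly one metadata row).
#' @return data frame: sample, age_months, tissue, group.
#' @export
read_metadata <- function(path, counts = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "age_months", "tissue")
  if (!all(need %in% names(df)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicate sample id in metadata: ",
         df$sample[duplicated(df$sample)][1L])
  if (any(!is.finite(df$age_months)) || any(df$age_months <= 0))
    stop("age_months must be positive")
  if (is.null(df$group)) df$group <- paste0(df$age_months, "m")
  if (!is.null(counts)) {
    unknown <- setdiff(df$sample, colnames(counts))
    if (length(unknown))
      stop("metadata sample(s) not in count matrix: ",
           paste(unknown, collapse = ", "))
    missing <- setdiff(colnames(counts), df$sample)
    if (length(missing))
      stop("count matrix column(s) without metadata: ",
           paste(missing, collapse = ", "))
  }
  df
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member ids.
#' Lines with fewer than 3 fields are rejected with their line number;
#' duplicate members within a set are deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return named list of gene-id vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1L])
  dup <- vapply(sets, anyDuplicated, integer(1L)) > 0L
  if (any(dup)) {
    warning("WARN [GMT_DUP_MEMBER] deduplicated members in set(s): ",
            paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  attr(sets, "description") <- vapply(fields, `[[`, character(1L), 2L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param description optional description per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR Ct table from TSV
#'
#' Requires columns `sample`, `age_months`, `target`, `replicate`, `ct`.
#'
#' @param path TSV file path.
#' @return data frame with the validated columns.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "age_months", "target", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0) || any(df$ct >= 45))
    stop("Ct values must be positive cycles below 45")
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects input paths, thresholds and contrast definitions for
#' [run_all()]. Contrasts default to the study design: E = 24m vs 2m,
#' L = 28m vs 24m, plus a 28m vs 2m contrast computed for reporting only.
#'
#' @param counts,metadata paths to the counts and metadata TSVs.
#' @param gmt optional GMT path; enrichment stages are skipped without it.
#' @param qpcr optional qPCR TSV path; the qPCR stage is skipped without it.
#' @param out_dir output directory (created if needed).
#' @param e_contrast,l_contrast,report_contrast `c(younger, older)` ages.
#' @param deg_fc,deg_p,deg_use_adjusted DEG-calling thresholds.
#' @param sig_alpha,nonsig_alpha phase-classification thresholds.
#' @param enrich_fdr,enrich_diff differential-enrichment thresholds.
#' @param min_set,max_set gene-set size bounds.
#' @param ntop top-variance gene count for PCA.
#' @param nperm permutations for the pre-ranked test.
#' @param seed RNG seed for permutation draws.
#' @return list of class `run_config`.
#' @export
run_config <- function(counts, metadata, gmt = NULL, qpcr = NULL,
                       out_dir = "results",
                       e_contrast = c(2, 24), l_contrast = c(24, 28),
                       report_contrast = c(2, 28),
                       deg_fc = 2, deg_p = 0.001, deg_use_adjusted = TRUE,
                       sig_alpha = 0.001, nonsig_alpha = 0.1,
                       enrich_fdr = 1e-5, enrich_diff = 0.5,
                       min_set = 5L, max_set = 500L,
                       ntop = 5000L, nperm = 1000L, seed = 1L) {
  stopifnot(sig_alpha > 0, sig_alpha < nonsig_alpha, nonsig_alpha <= 1,
            deg_fc > 0, deg_p > 0, enrich_fdr > 0, enrich_diff >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full age-course analysis pipeline
#'
#' Normalization, differential expression on the three contrasts, phase
#' classification with EL subtyping, trajectory distances / divergence
#' rates / PCA, enrichment (pre-ranked on the late-contrast ranking,
#' per-sample scores with differential enrichment between the two oldest
#' groups, over-representation of downturn and upturn genes), and the qPCR
#' copy-number stage when a plate is supplied. All tables are written as
#' TSV under `config$out_dir` together with a manifest and a JSON summary;
#' identical config and seed give byte-identical outputs.
#'
#' @param config a [run_config()] object.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "read_inputs"
  on_fail <- function(e) {
    writeLines(c(paste("FAILED at stage:", stage), conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    counts <- read_counts(config$counts)
    metadata <- read_metadata(config$metadata, counts)
    sets <- if (!is.null(config$gmt)) read_gmt(config$gmt)
    qpcr <- if (!is.null(config$qpcr)) read_qpcr(config$qpcr)
    outputs <- character()
    emit <- function(df, name) {
      p <- file.path(config$out_dir, name)
      write_tsv(df, p)
      outputs <<- c(outputs, name)
    }

    stage <- "normalization"
    factors <- size_factors(counts)
    groups <- metadata$age_months[match(colnames(counts), metadata$sample)]
    dispersion <- estimate_dispersion(counts, factors, groups)
    norm <- normalize_counts(counts, factors)

    stage <- "differential_expression"
    contrasts <- list(E = config$e_contrast, L = config$l_contrast,
                      report = config$report_contrast)
    de <- lapply(contrasts, function(ct)
      de_contrast(counts, metadata, ct[1L], ct[2L],
                  factors = factors, dispersion = dispersion))
    for (d in de) emit(d, paste0("de_", attr(d, "contrast"), ".tsv"))
    degs <- lapply(de, call_degs, fc_threshold = config$deg_fc,
                   p_threshold = config$deg_p,
                   use_adjusted = config$deg_use_adjusted)

    stage <- "phase_classification"
    labels <- subtype_el(classify_phases(de$E, de$L, config$sig_alpha,
                                         config$nonsig_alpha))
    emit(labels, "phase_labels.tsv")
    summary_cls <- class_summary(labels)

    stage <- "trajectory"
    trans <- log_transform(norm)
    profiles <- group_mean_profiles(trans, metadata)
    d <- pairwise_group_distance(profiles)
    rates <- divergence_rates(d)
    youngest <- paste0(min(metadata$age_months), "m")
    reversion <- reversion_index(d, youngest)
    wgv <- within_group_variance(trans, metadata)
    pca <- pca_scores(trans, config$ntop)
    emit(data.frame(group = rownames(d), d, check.names = FALSE),
         "distance_matrix.tsv")
    emit(rates$rates, "divergence_rates.tsv")
    emit(data.frame(sample = rownames(pca$scores),
                    pca$scores[, seq_len(min(5L, ncol(pca$scores))),
                               drop = FALSE],
                    check.names = FALSE), "pc_scores.tsv")

    stage <- "enrichment"
    enr <- NULL
    if (!is.null(sets)) {
      ranked <- rank_genes(de$L)
      enr_pre <- preranked_test(ranked, sets, nperm = config$nperm,
                                seed = config$seed,
                                min_size = config$min_set,
                                max_size = config$max_set)
      emit(enr_pre, "gsea_preranked.tsv")
      old_ages <- c(config$l_contrast[1L], config$l_contrast[2L])
      old_samples <- metadata$sample[metadata$age_months %in% old_ages]
      scores <- per_sample_scores(trans[, old_samples, drop = FALSE], sets,
                                  min_size = config$min_set,
                                  max_size = config$max_set)
      grp <- stats::setNames(
        metadata$age_months[match(old_samples, metadata$sample)], old_samples)
      enr_diff <- differential_enrichment(scores, grp, old_ages[1L],
                                          old_ages[2L],
                                          fdr_threshold = config$enrich_fdr,
                                          diff_threshold = config$enrich_diff)
      emit(enr_diff, "differential_enrichment.tsv")
      emit(data.frame(sample = rownames(scores), scores, check.names = FALSE),
           "sample_scores.tsv")
      universe <- rownames(counts)
      for (sub in c("downturn", "upturn")) {
        hits <- labels$gene[labels$el_subtype == sub]
        emit(overrepresentation_test(hits, universe, sets),
             paste0("ora_", sub, ".tsv"))
      }
      enr <- list(preranked = enr_pre, differential = enr_diff,
                  scores = scores)
    } else {
      message("INFO: no GMT supplied; enrichment stage skipped")
    }

    stage <- "qpcr"
    copy <- NULL
    if (!is.null(qpcr)) {
      copy <- mito_copy_ratio(qpcr)
      emit(copy$samples, "qpcr_copy_ratio.tsv")
      emit(copy$groups, "qpcr_copy_groups.tsv")
    } else {
      message("INFO: no qPCR table supplied; qpcr stage skipped")
    }

    stage <- "summarize"
    summary <- list(
      n_genes = nrow(counts), n_samples = ncol(counts),
      contrasts = lapply(de, attr, which = "contrast"),
      n_degs = lapply(degs, length),
      phase_counts = as.list(summary_cls$counts),
      el_subtype_counts = as.list(summary_cls$subtype_counts),
      phase_fractions = as.list(summary_cls$fractions),
      nearest_to_youngest = reversion$nearest,
      rate_ratio = rates$rate_ratio,
      within_group_distance = as.list(wgv),
      pc_variance_fractions = pca$var_frac[seq_len(min(5L,
                                                       length(pca$var_frac)))],
      n_enriched_called = if (!is.null(enr)) sum(enr$differential$called)
                          else NA)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, "summary.json")

    cfg_for_hash <- config
    cfg_for_hash$out_dir <- NULL
    hash_file <- tempfile()
    jsonlite::write_json(cfg_for_hash, hash_file, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    manifest <- list(
      inputs = list(counts = config$counts, metadata = config$metadata,
                    gmt = config$gmt, qpcr = config$qpcr),
      config_hash = unname(tools::md5sum(hash_file)),
      seed = config$seed,
      stages_skipped = c(if (is.null(sets)) "enrichment",
                         if (is.null(qpcr)) "qpcr"),
      package_version = as.character(utils::packageVersion("agephase")),
      outputs = outputs)
    unlink(hash_file)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(de = de, degs = degs, labels = labels,
                   summary = summary_cls, distance = d, rates = rates,
                   reversion = reversion, within_group = wgv, pca = pca,
                   enrichment = enr, copy = copy, manifest = manifest))
  }, error = on_fail)
}
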