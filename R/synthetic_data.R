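#' Configuration for the synthetic age-course generator
#'
#' Builds the configuration object consumed by [simulate_counts()],
#' [simulate_gene_sets()] and [simulate_qpcr_plate()]. Defaults emulate the
#' mouse skeletal-muscle study design: five age groups (2, 10, 18, 24, 28
#' months), negative-binomial counts with sample-specific library-size
#' factors and gene-wise dispersion, and planted gene classes whose log2
#' fold changes are anchored on the early aging interval (E: youngest to
#' second-oldest age, i.e. 2 to 24 months) and the late interval (L:
#' second-oldest to oldest age, i.e. 24 to 28 months).
#'
#' Planted classes and their (lfc_E, lfc_L) signs, with `e = effect_lfc`:
#' `null` (0, 0); `E_up` (+e, 0); `E_down` (-e, 0); `L_up` (0, +e);
#' `L_down` (0, -e); `EL_downturn` (+e, -e); `EL_upturn` (-e, +e);
#' `cont_up` (+e, +e); `cont_down` (-e, -e).
#'
#' @param n_genes number of genes.
#' @param ages strictly increasing vector of ages in months.
#' @param n_per_group replicates per age group; scalar or one value per age.
#' @param base_mean_meanlog,base_mean_sdlog log-normal location/scale of the
#'   per-gene baseline expression mean.
#' @param dispersion_target mean of the gamma-distributed per-gene NB
#'   dispersion alpha (variance = mu + alpha * mu^2).
#' @param dispersion_shape gamma shape; larger means tighter around target.
#' @param class_counts named integer vector of genes per planted class
#'   (names among the non-null classes above); remaining genes are null.
#' @param effect_lfc planted log2 fold-change magnitude per interval.
#' @param libsize_range range of the log-uniform library-size factors.
#' @param n_coordinated_sets,n_random_sets gene-set counts for
#'   [simulate_gene_sets()].
#' @param set_size_range inclusive bounds on gene-set sizes.
#' @param coupling logical; couple the planted mitochondrial copy-number
#'   trajectory to the mean planted expression of the `EL_downturn` class.
#' @param qpcr_replicates technical replicates per (sample, target).
#' @param qpcr_noise_sd replicate Ct noise, in cycles.
#' @param seed master RNG seed; substreams for counts, gene sets and qPCR
#'   are derived from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000L,
                       ages = c(2L, 10L, 18L, 24L, 28L),
                       n_per_group = 6L,
                       base_mean_meanlog = log(200),
                       base_mean_sdlog = 1,
                       dispersion_target = 0.05,
                       dispersion_shape = 20,
                       class_counts = c(E_up = 200L, E_down = 200L,
                                        L_up = 200L, L_down = 200L,
                                        EL_downturn = 200L, EL_upturn = 200L,
                                        cont_up = 200L, cont_down = 200L),
                       effect_lfc = 2,
                       libsize_range = c(0.5, 2),
                       n_coordinated_sets = 8L,
                       n_random_sets = 8L,
                       set_size_range = c(20L, 80L),
                       coupling = TRUE,
                       qpcr_replicates = 3L,
                       qpcr_noise_sd = 0.15,
                       seed = 1L) {
  if (length(ages) < 2L || any(diff(ages) <= 0))
    stop("`ages` must be strictly increasing with at least two values")
  if (effect_lfc <= 0) stop("`effect_lfc` must be positive")
  if (dispersion_target <= 0) stop("`dispersion_target` must be positive")
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, length(ages))
  if (length(n_per_group) != length(ages))
    stop("`n_per_group` must be scalar or one value per age")
  if (any(n_per_group < 1L)) stop("each age group needs at least one sample")
  class_counts <- class_counts[class_counts > 0]
  known <- c("E_up", "E_down", "L_up", "L_down",
             "EL_downturn", "EL_upturn", "cont_up", "cont_down")
  if (length(class_counts) && !all(names(class_counts) %in% known))
    stop("unknown class in `class_counts`: ",
         paste(setdiff(names(class_counts), known), collapse = ", "))
  if (sum(class_counts) > n_genes)
    stop("`class_counts` sum (", sum(class_counts),
         ") exceeds `n_genes` (", n_genes, ")")
  if (qpcr_noise_sd < 0) stop("`qpcr_noise_sd` must be nonnegative")
  cfg <- list(n_genes = as.integer(n_genes), ages = as.numeric(ages),
              n_per_group = as.integer(n_per_group),
              base_mean_meanlog = base_mean_meanlog,
              base_mean_sdlog = base_mean_sdlog,
              dispersion_target = dispersion_target,
              dispersion_shape = dispersion_shape,
              class_counts = class_counts, effect_lfc = effect_lfc,
              libsize_range = libsize_range,
              n_coordinated_sets = as.integer(n_coordinated_sets),
              n_random_sets = as.integer(n_random_sets),
              set_size_range = as.integer(set_size_range),
              coupling = isTRUE(coupling),
              qpcr_replicates = as.integer(qpcr_replicates),
              qpcr_noise_sd = qpcr_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Derived per-purpose substream seeds (kept below 2^31).
sub_seed <- function(seed, purpose) {
  offset <- c(counts = 101L, sets = 202L, qpcr = 303L, truth = 404L)[[purpose]]
  (as.integer(seed) %% 20000000L) * 100L + offset
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Fraction of the E (resp. L) effect accrued at each age: linear in log2
# space from the youngest to the second-oldest age, then from the
# second-oldest to the oldest.
effect_fractions <- function(ages) {
  young <- ages[1L]
  oo <- ages[length(ages)]
  if (length(ages) == 2L) {
    # two-age design: a single interval carries the whole E effect
    return(list(e = c(0, 1), l = c(0, 0)))
  }
  yo <- ages[length(ages) - 1L]
  frac_e <- pmin(pmax((ages - young) / (yo - young), 0), 1)
  frac_l <- pmin(pmax((ages - yo) / (oo - yo), 0), 1)
  list(e = frac_e, l = frac_l)
}

# Planted (lfc_E, lfc_L) for each class at magnitude e.
class_lfc_table <- function(e) {
  rbind(null        = c(0, 0),
        E_up        = c(e, 0),
        E_down      = c(-e, 0),
        L_up        = c(0, e),
        L_down      = c(0, -e),
        EL_downturn = c(e, -e),
        EL_upturn   = c(-e, e),
        cont_up     = c(e, e),
        cont_down   = c(-e, -e))
}

#' Simulate an age-course count matrix with planted truth
#'
#' Draws negative-binomial counts with mean
#' `base_mean_g * sizefactor_s * 2^(cumulative planted lfc at age_s)` and
#' variance `mu + alpha_g * mu^2`. Intermediate ages interpolate the E-interval
#' effect linearly in log2 space between the youngest and second-oldest ages.
#'
#' @param config a [sim_config()] object.
#' @param truth optional truth table (data frame with columns `gene`,
#'   `class`, `lfc_e`, `lfc_l`) overriding the class-based planting; must
#'   cover `config$n_genes` genes. Used to plant bespoke drift patterns.
#' @return list with `counts` (integer matrix, genes x samples), `metadata`
#'   (data frame: sample, age_months, tissue, group), `truth` (data frame:
#'   gene, class, lfc_e, lfc_l) and `size_factors` (the true planted
#'   factors).
#' @export
simulate_counts <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_genes <- config$n_genes
  ages <- config$ages
  gene_ids <- sprintf("g%05d", seq_len(n_genes))

  if (is.null(truth)) {
    classes <- rep("null", n_genes)
    cc <- config$class_counts
    if (length(cc)) {
      idx <- 0L
      for (cl in names(cc)) {
        classes[idx + seq_len(cc[[cl]])] <- cl
        idx <- idx + cc[[cl]]
      }
    }
    lt <- class_lfc_table(config$effect_lfc)
    truth <- data.frame(gene = gene_ids, class = classes,
                        lfc_e = lt[classes, 1L], lfc_l = lt[classes, 2L],
                        stringsAsFactors = FALSE)
  } else {
    if (nrow(truth) != n_genes)
      stop("`truth` must have one row per gene (", n_genes, ")")
    truth$gene <- gene_ids
  }
  rownames(truth) <- NULL

  n_per <- config$n_per_group
  sample_age <- rep(ages, n_per)
  sample_rep <- unlist(lapply(n_per, seq_len))
  sample_ids <- sprintf("a%02d_r%d", sample_age, sample_rep)
  metadata <- data.frame(sample = sample_ids,
                         age_months = sample_age,
                         tissue = "muscle",
                         group = paste0(sample_age, "m"),
                         stringsAsFactors = FALSE)

  fr <- effect_fractions(ages)
  # cumulative planted lfc: genes x ages
  cum_lfc <- outer(truth$lfc_e, fr$e) + outer(truth$lfc_l, fr$l)

  counts <- with_seed(sub_seed(config$seed, "counts"), {
    base_mean <- stats::rlnorm(n_genes, config$base_mean_meanlog,
                               config$base_mean_sdlog)
    alpha <- stats::rgamma(n_genes, shape = config$dispersion_shape,
                           rate = config$dispersion_shape / config$dispersion_target)
    sf <- exp(stats::runif(length(sample_ids),
                           log(config$libsize_range[1L]),
                           log(config$libsize_range[2L])))
    age_col <- match(sample_age, ages)
    mu <- (base_mean * 2^cum_lfc[, age_col, drop = FALSE]) *
      rep(sf, each = n_genes)
    m <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / alpha),
                nrow = n_genes,
                dimnames = list(gene_ids, sample_ids))
    attr(m, "base_mean") <- base_mean
    attr(m, "alpha") <- alpha
    attr(m, "sf") <- sf
    m
  })
  sf <- attr(counts, "sf")
  names(sf) <- sample_ids
  base_mean <- attr(counts, "base_mean")
  alpha <- attr(counts, "alpha")
  attr(counts, "sf") <- NULL
  attr(counts, "base_mean") <- NULL
  attr(counts, "alpha") <- NULL

  list(counts = counts, metadata = metadata, truth = truth,
       size_factors = sf,
       base_mean = stats::setNames(base_mean, gene_ids),
       dispersion = stats::setNames(alpha, gene_ids))
}

#' Simulate gene-set collections with planted coordination
#'
#' Emits "coordinated" sets, each drawn from a single planted class, and
#' "random" sets drawn uniformly from the gene universe.
#'
#' @param truth truth table from [simulate_counts()].
#' @param config a [sim_config()] object.
#' @return list with `sets` (named list of gene-id vectors) and `info`
#'   (data frame: set, type, class, size).
#' @export
simulate_gene_sets <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  lo <- config$set_size_range[1L]
  hi <- config$set_size_range[2L]
  if (lo < 1L) stop("set sizes must be at least 1")
  classes <- names(config$class_counts)
  if (config$n_coordinated_sets > 0L && length(classes) == 0L)
    stop("coordinated sets requested but no planted classes configured")

  with_seed(sub_seed(config$seed, "sets"), {
    sets <- list()
    info <- list()
    draw_size <- function() if (lo == hi) lo else sample(seq(lo, hi), 1L)
    for (i in seq_len(config$n_coordinated_sets)) {
      cl <- classes[((i - 1L) %% length(classes)) + 1L]
      members_pool <- truth$gene[truth$class == cl]
      size <- draw_size()
      if (size > length(members_pool))
        stop("requested coordinated set of size ", size,
             " but class '", cl, "' has only ", length(members_pool), " genes")
      nm <- sprintf("coord_%s_%02d", cl, i)
      sets[[nm]] <- sort(sample(members_pool, size))
      info[[nm]] <- data.frame(set = nm, type = "coordinated", class = cl,
                               size = size, stringsAsFactors = FALSE)
    }
    for (i in seq_len(config$n_random_sets)) {
      size <- draw_size()
      nm <- sprintf("random_%02d", i)
      sets[[nm]] <- sort(sample(truth$gene, size))
      info[[nm]] <- data.frame(set = nm, type = "random", class = NA_character_,
                               size = size, stringsAsFactors = FALSE)
    }
    list(sets = sets, info = do.call(rbind, c(info, list(make.row.names = FALSE))))
  })
}

#' Planted mitochondrial copy-number trajectory
#'
#' When coupling is on, the planted log2 copy ratio tracks the mean planted
#' log2 expression shift of the `EL_downturn` class (a downturn shape);
#' otherwise it is flat.
#'
#' @param config a [sim_config()] object.
#' @param base_log2_ratio baseline log2 mito/nuclear copy ratio (muscle
#'   carries on the order of 2^10 mitochondrial genomes per nuclear genome).
#' @return numeric vector of planted log2 ratios, one per age.
#' @export
planted_copy_trajectory <- function(config, base_log2_ratio = 10) {
  fr <- effect_fractions(config$ages)
  if (config$coupling) {
    e <- config$effect_lfc
    shift <- e * fr$e - e * fr$l  # EL_downturn cumulative lfc per age
  } else {
    shift <- rep(0, length(config$ages))
  }
  stats::setNames(base_log2_ratio + shift, paste0(config$ages, "m"))
}

#' Simulate a qPCR plate for mitochondrial copy-number quantification
#'
#' Generates replicate Ct values for a mitochondrial target and a
#' nuclear-encoded single-copy reference per sample. The planted copy ratio
#' enters as `Ct_mito = Ct_nuclear - log2(ratio)` before replicate noise.
#'
#' @param config a [sim_config()] object.
#' @param base_log2_ratio passed to [planted_copy_trajectory()].
#' @param nuclear_ct mean nuclear-reference Ct, cycles.
#' @return data frame: sample, age_months, target (`mito`/`nuclear`),
#'   replicate, ct; the planted per-age log2 ratios are attached as
#'   attribute `planted_log2_ratio`.
#' @export
simulate_qpcr_plate <- function(config, base_log2_ratio = 10, nuclear_ct = 26) {
  stopifnot(inherits(config, "sim_config"))
  traj <- planted_copy_trajectory(config, base_log2_ratio)
  ages <- config$ages
  n_per <- config$n_per_group
  sample_age <- rep(ages, n_per)
  sample_ids <- sprintf("a%02d_r%d", sample_age, unlist(lapply(n_per, seq_len)))
  nrep <- config$qpcr_replicates
  grid <- expand.grid(replicate = seq_len(nrep),
                      target = c("mito", "nuclear"),
                      sample = sample_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$age_months <- sample_age[match(grid$sample, sample_ids)]
  planted <- traj[match(paste0(grid$age_months, "m"), names(traj))]
  true_ct <- ifelse(grid$target == "nuclear", nuclear_ct, nuclear_ct - planted)
  ct <- with_seed(sub_seed(config$seed, "qpcr"),
                  true_ct + stats::rnorm(length(true_ct), 0, config$qpcr_noise_sd))
  out <- data.frame(sample = grid$sample, age_months = grid$age_months,
                    target = grid$target, replicate = grid$replicate,
                    ct = ct, stringsAsFactors = FALSE)
  attr(out, "planted_log2_ratio") <- traj
  out
}
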