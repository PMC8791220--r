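# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results from first principles and
# share no code with the implementation under test.

# Textbook step-up FDR adjustment: sort ascending, padj_(i) = min over
# j >= i of n * p_(j) / j, capped at 1, mapped back to input order.
bh_stepup_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  padj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    padj_sorted[i] <- min(1, min(n * p[ord][i:n] / (i:n)))
  }
  padj <- numeric(n)
  padj[ord] <- padj_sorted
  padj
}

# Position-by-position running-sum enumeration of the weighted enrichment
# score; returns the value of largest absolute magnitude.
es_bruteforce <- function(stats, set, weight = 1) {
  n <- length(stats)
  hits <- names(stats) %in% set
  w <- abs(stats)^weight
  denom_hit <- sum(w[hits])
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hits[i]) {
      run <- run + (if (denom_hit > 0) w[i] / denom_hit else 1 / sum(hits))
    } else {
      run <- run - 1 / (n - sum(hits))
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Exhaustive enumeration of the hypergeometric upper tail: over all
# possible draws of `length(gene_list)` genes from the universe, the
# fraction whose overlap with `set` is at least the observed overlap.
hypergeom_enumerate <- function(gene_list, set, universe) {
  k <- length(gene_list)
  obs <- length(intersect(gene_list, set))
  draws <- utils::combn(universe, k)
  hits <- apply(draws, 2L, function(d) length(intersect(d, set)) >= obs)
  mean(hits)
}

# Small deterministic count fixture: `n_genes` x (2 groups x n) Poisson
# counts around `mu`, with optional fold change on group B.
toy_two_group_counts <- function(n_genes = 50, n = 4, mu = 100, fc_b = 1,
                                 seed = 1) {
  set.seed(seed)
  a <- matrix(rpois(n_genes * n, mu), nrow = n_genes)
  b <- matrix(rpois(n_genes * n, mu * fc_b), nrow = n_genes)
  counts <- cbind(a, b)
  rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
  colnames(counts) <- c(sprintf("a%d", seq_len(n)), sprintf("b%d", seq_len(n)))
  counts
}

# Full default pipeline on a simulation: DE on both intervals plus labels.
run_phase_pipeline <- function(sim) {
  f <- size_factors(sim$counts)
  disp <- estimate_dispersion(sim$counts, f, sim$metadata$age_months)
  ages <- sort(unique(sim$metadata$age_months))
  k <- length(ages)
  de_e <- de_contrast(sim$counts, sim$metadata, ages[1L], ages[k - 1L],
                      factors = f, dispersion = disp)
  de_l <- de_contrast(sim$counts, sim$metadata, ages[k - 1L], ages[k],
                      factors = f, dispersion = disp)
  labels <- subtype_el(classify_phases(de_e, de_l))
  list(factors = f, dispersion = disp, de_e = de_e, de_l = de_l,
       labels = labels)
}

# Expected phase implied by each planted class.
truth_phase <- function(class) {
  c(null = "none", E_up = "E", E_down = "E", L_up = "L", L_down = "L",
    EL_downturn = "EL", EL_upturn = "EL", cont_up = "EL",
    cont_down = "EL")[class]
}
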