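#!/usr/bin/env Rscript
# Differential expression across the three age contrasts: the early aging
# interval (24m vs 2m), the late interval (28m vs 24m), and the full-span
# 28m vs 2m comparison reported for reference. Counts are normalized by
# median-of-ratios size factors and tested gene-wise with a
# negative-binomial Wald test using method-of-moments dispersions pooled
# across all five groups.

suppressMessages(library(agephase))
counts <- read_counts("results/data/counts.tsv")
metadata <- read_metadata("results/data/metadata.tsv", counts)

factors <- size_factors(counts)
dispersion <- estimate_dispersion(counts, factors, metadata$age_months)
message("size factor range: ", paste(round(range(factors), 3), collapse = " - "))
message("median dispersion estimate: ", signif(median(dispersion), 3))

contrasts <- list(c(2, 24), c(24, 28), c(2, 28))
for (ct in contrasts) {
  de <- de_contrast(counts, metadata, ct[1], ct[2], factors = factors,
                    dispersion = dispersion)
  name <- attr(de, "contrast")
  write.table(de, sprintf("results/de_%s.tsv", name), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # the two DEG definitions in use: the volcano criterion (fold change > 2,
  # raw p < 1e-5) and the stricter default (fold change > 2, padj < 0.001)
  n_volcano <- length(call_degs(de, 2, 1e-5, use_adjusted = FALSE))
  n_default <- length(call_degs(de, 2, 0.001, use_adjusted = TRUE))
  message(sprintf("%s: %d DEGs (raw p < 1e-5), %d DEGs (padj < 0.001)",
                  name, n_volcano, n_default))
}
message("wrote results/de_*.tsv")
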