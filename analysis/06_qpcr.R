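#!/usr/bin/env Rscript
# Mitochondrial DNA copy number across the age course: per-sample
# mito/nuclear copy ratios from the qPCR plate by 2^(Ct_nuclear - Ct_mito),
# group summaries per age, and the Pearson correlation between the
# per-age mean copy ratio and the mean expression of the planted
# mitochondrial (EL downturn) gene set.

suppressMessages(library(agephase))
counts <- read_counts("results/data/counts.tsv")
metadata <- read_metadata("results/data/metadata.tsv", counts)
plate <- read_qpcr("results/data/qpcr.tsv")
truth <- read.delim("results/data/truth.tsv")

copy <- mito_copy_ratio(plate)
write.table(copy$samples, "results/qpcr_copy_ratio.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(copy$groups, "results/qpcr_copy_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("mito/nuclear copy ratio by age group:")
print(copy$groups, digits = 4)

trans <- log_transform(normalize_counts(counts, size_factors(counts)))
set <- truth$gene[truth$class == "EL_downturn"]
r <- correlate_with_set_mean(copy, trans, metadata, set)
message(sprintf("Pearson r between group mean copy ratio and mean %s-set expression: %.3f (n = %d age groups)",
                "EL-downturn", r$r, r$n_groups))
print(r$values, digits = 4)
jsonlite::write_json(list(r = r$r, n_groups = r$n_groups),
                     "results/qpcr_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote results/qpcr_copy_*.tsv and qpcr_summary.json")
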