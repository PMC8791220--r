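#!/usr/bin/env Rscript
# Generate the synthetic age-course study bundle: a 10,000-gene count
# matrix over 2/10/18/24/28-month groups (6 mice each) with planted aging
# classes, coordinated and random gene sets, and a coupled qPCR plate for
# mitochondrial copy number. All downstream scripts read these files.

suppressMessages(library(agephase))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1L)  # defaults: 200 genes per planted class
sim <- simulate_counts(cfg)
gs <- simulate_gene_sets(sim$truth, cfg)
plate <- simulate_qpcr_plate(cfg)

write_counts(sim$counts, "results/data/counts.tsv")
write.table(sim$metadata, "results/data/metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth, "results/data/truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gmt(gs$sets, "results/data/gene_sets.gmt")
write.table(gs$info, "results/data/gene_set_info.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(plate, "results/data/qpcr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("samples per age group:")
print(table(sim$metadata$age_months))
message("planted classes:")
print(table(sim$truth$class))
message("wrote results/data/{counts,metadata,truth,gene_set_info,qpcr}.tsv ",
        "and gene_sets.gmt")
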