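#!/usr/bin/env Rscript
# Gene-set inference on the late aging interval: pre-ranked enrichment on
# the 28m-vs-24m fold-change ranking with permutation p-values, per-sample
# enrichment scores with differential-enrichment calls between the 24m and
# 28m groups (padj < 1e-5 and |score difference| > 0.5), and hypergeometric
# over-representation of the downturn and upturn EL-aging gene lists.

suppressMessages(library(agephase))
counts <- read_counts("results/data/counts.tsv")
metadata <- read_metadata("results/data/metadata.tsv", counts)
sets <- read_gmt("results/data/gene_sets.gmt")
info <- read.delim("results/data/gene_set_info.tsv")
de_l <- read.delim("results/de_28m_vs_24m.tsv")
labels <- read.delim("results/phase_labels.tsv")

ranked <- rank_genes(de_l)
pre <- preranked_test(ranked, sets, nperm = 1000, seed = 1)
write.table(pre, "results/gsea_preranked.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- pre[pre$padj < 0.05, ]
message(sprintf("pre-ranked: %d/%d sets at padj < 0.05 (%d enriched, %d depleted in 28m)",
                nrow(sig), nrow(pre), sum(sig$direction == "enriched"),
                sum(sig$direction == "depleted")))

factors <- size_factors(counts)
trans <- log_transform(normalize_counts(counts, factors))
old <- metadata$sample[metadata$age_months %in% c(24, 28)]
scores <- per_sample_scores(trans[, old], sets)
write.table(data.frame(sample = rownames(scores), scores,
                       check.names = FALSE),
            "results/sample_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
grp <- setNames(metadata$age_months[match(old, metadata$sample)], old)
calls <- differential_enrichment(scores, grp, 24, 28,
                                 fdr_threshold = 1e-5, diff_threshold = 0.5)
write.table(calls, "results/differential_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
called <- calls[calls$called, ]
message(sprintf("differential enrichment: %d sets called (%d enriched, %d depleted in 28m)",
                nrow(called), sum(called$direction == "enriched"),
                sum(called$direction == "depleted")))
message("called sets by planted type:")
print(table(info$type[match(called$set, info$set)]))

universe <- rownames(counts)
for (sub in c("downturn", "upturn")) {
  hits <- labels$gene[labels$el_subtype == sub]
  ora <- overrepresentation_test(hits, universe, sets)
  write.table(ora, sprintf("results/ora_%s.tsv", sub), sep = "\t",
              quote = FALSE, row.names = FALSE)
  top <- ora[order(ora$pvalue), ][1:3, ]
  message(sprintf("%s genes (n = %d): top over-represented sets %s",
                  sub, length(hits),
                  paste(sprintf("%s (%d/%d, padj %.2g)", top$set,
                                top$overlap, top$set_size, top$padj),
                        collapse = "; ")))
}
message("wrote results/{gsea_preranked,sample_scores,differential_enrichment,ora_*}.tsv")
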