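#!/usr/bin/env Rscript
# Classify every gene by aging phase from the two interval contrasts:
# E (changed in 2->24m only), L (24->28m only), EL (both, in a row), none.
# EL genes are subtyped by trajectory shape (downturn, upturn, continuous),
# and the labels are scored against the planted truth.

suppressMessages(library(agephase))
de_e <- read.delim("results/de_24m_vs_2m.tsv")
de_l <- read.delim("results/de_28m_vs_24m.tsv")
truth <- read.delim("results/data/truth.tsv")

labels <- subtype_el(classify_phases(de_e, de_l,
                                     sig_alpha = 0.001, nonsig_alpha = 0.1))
write.table(labels, "results/phase_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
s <- class_summary(labels)
jsonlite::write_json(list(counts = as.list(s$counts),
                          subtype_counts = as.list(s$subtype_counts),
                          fractions = as.list(s$fractions)),
                     "results/phase_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

message("phase counts:")
print(s$counts)
message("EL subtype counts:")
print(s$subtype_counts)
message(sprintf("EL-aging genes: %d (%.1f%% of the universe)",
                s$counts[["EL"]], 100 * s$fractions[["EL"]]))

# recovery against planted truth
expected <- c(null = "none", E_up = "E", E_down = "E", L_up = "L",
              L_down = "L", EL_downturn = "EL", EL_upturn = "EL",
              cont_up = "EL", cont_down = "EL")[truth$class]
called <- labels$phase != "none"
message(sprintf("sensitivity EL_downturn: %.3f; EL_upturn: %.3f; label FDR: %.4f",
  mean(labels$el_subtype[truth$class == "EL_downturn"] == "downturn"),
  mean(labels$el_subtype[truth$class == "EL_upturn"] == "upturn"),
  mean(labels$phase[called] != expected[called])))

# sensitivity re-count under the relaxed significance cut
relaxed <- classify_phases(de_e, de_l, sig_alpha = 0.05, nonsig_alpha = 0.1)
message(sprintf("EL count at padj < 0.001: %d; at padj < 0.05: %d",
                sum(labels$phase == "EL"), sum(relaxed$phase == "EL")))
message("wrote results/phase_labels.tsv and results/phase_summary.json")
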