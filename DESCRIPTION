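Package: agephase
Title: Aging-Phase Classification and Trajectory Analysis for Age-Course Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq age courses that distinguishes
    an early/gradual from a late/accelerated aging phase in mouse skeletal
    muscle. Provides negative-binomial Wald differential expression between
    age groups with median-of-ratios normalization, classification of genes
    into early (E), late (L) and biphasic (EL) aging categories with
    downturn/upturn subtypes, Euclidean transcriptomic distances and
    per-month divergence rates along the age trajectory, pre-ranked and
    per-sample rank-based gene-set enrichment with differential-enrichment
    calling, hypergeometric over-representation tests, and delta-delta-Ct
    quantification of mitochondrial DNA copy number from qPCR plates. A
    synthetic-data module generates age-course count matrices, gene sets and
    qPCR plates with planted truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    DESeq2
Config/testthat/edition: 3
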