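#!/usr/bin/env Rscript
# Differential expression on the simulated RNA-seq counts: low-expression
# filtering (drop a gene when >= 90% of samples have a count below 2),
# NB Wald test with BH correction, significance at padj <= 0.05 and
# |log2FC| >= 1, plus FPKM for the linking step.

library(acetylink)

indir <- "results/sim"
counts <- read_count_table(file.path(indir, "rna_counts.tsv"))
totals <- read.delim(file.path(indir, "totals.tsv"))
groups <- factor(totals$group, levels = unique(totals$group))
ann <- parse_annotation(file.path(indir, "annotation.gtf"))
exlen <- tapply(ann$exons$end - ann$exons$start, ann$exons$gene_id, sum)

filtered <- filter_low_expression(counts)
cat("Filtered", nrow(counts) - nrow(filtered), "lowly expressed gene(s);",
    nrow(filtered), "tested\n")

res <- nb_wald_test(filtered, groups)
fp <- fpkm(filtered, as.numeric(exlen[rownames(filtered)]))

dir.create("results", showWarnings = FALSE)
write_tsv(res, "results/rnaseq_diff.tsv")
write_count_table(fp, "results/rna_fpkm.tsv", id_col = "gene_id")

cat("DEGs (padj <= 0.05, |log2FC| >= 1):", sum(res$direction != "ns"),
    "(", sum(res$direction == "up"), "up /",
    sum(res$direction == "down"), "down in FLHS )\n")
truth <- read.delim(file.path(indir, "truth_genes.tsv"))
called <- res$feature[res$direction != "ns"]
cat("Planted DE genes recovered:", sum(truth$gene_id %in% called), "of",
    nrow(truth), "\n")
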