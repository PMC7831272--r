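#!/usr/bin/env Rscript
# qPCR validation arithmetic on bundled synthetic Ct tables: percent of
# input and fold enrichment over a negative locus for ChIP-qPCR, and
# 2^-ddCt relative expression (target normalized to a housekeeping gene,
# FLHS relative to control) for RT-qPCR.

library(acetylink)

chip <- read.delim(system.file("extdata", "synthetic_chip_qpcr.tsv",
                               package = "acetylink"))
chip$percent_input <- percent_input(chip$ct_chip, chip$ct_input,
                                    chip$input_fraction)
chip$dct <- chip$ct_chip - (chip$ct_input - log2(1 / chip$input_fraction))

# fold enrichment of each locus over the negative-control locus, per
# condition, from mean delta-Ct across replicates
dct_mean <- aggregate(dct ~ locus + condition, chip, mean)
neg <- dct_mean[dct_mean$locus == "negctrl", c("condition", "dct")]
fe <- dct_mean[dct_mean$locus != "negctrl", ]
fe$fold_enrichment <- fold_enrichment(
  fe$dct, neg$dct[match(fe$condition, neg$condition)])

dir.create("results", showWarnings = FALSE)
write_tsv(chip, "results/chip_qpcr_percent_input.tsv")
write_tsv(fe[, c("locus", "condition", "fold_enrichment")],
          "results/chip_qpcr_fold_enrichment.tsv")
cat("ChIP-qPCR fold enrichment over the negative locus:\n")
print(fe[, c("locus", "condition", "fold_enrichment")], row.names = FALSE)

rt <- read.delim(system.file("extdata", "synthetic_rt_qpcr.tsv",
                             package = "acetylink"))
ct_mean <- aggregate(cbind(ct_target, ct_reference) ~ gene + condition, rt, mean)
ctl <- ct_mean[ct_mean$condition == "control", ]
cases <- ct_mean[ct_mean$condition == "FLHS", ]
i <- match(cases$gene, ctl$gene)
cases$rel_expression <- relative_expression(
  cases$ct_target, cases$ct_reference, ctl$ct_target[i], ctl$ct_reference[i])
write_tsv(cases[, c("gene", "rel_expression")],
          "results/rt_qpcr_relative_expression.tsv")
cat("\nRT-qPCR relative expression (FLHS vs control, 2^-ddCt):\n")
print(cases[, c("gene", "rel_expression")], row.names = FALSE)
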