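#!/usr/bin/env Rscript
# Differential H3K27ac: merge the per-sample peak calls by the 1 kb summit
# criterion, normalize ChIP and input coverage by depth (per million) and
# peak length (per kb), subtract input, and call hyper-/hypo-acetylated
# regions (FLHS vs control) at raw p < 0.05 and |log2FC| >= 1. Peaks are
# also classified against the annotation (proximal/distal, genomic feature).

library(acetylink)

indir <- "results/sim"
ann <- parse_annotation(file.path(indir, "annotation.gtf"))
totals <- read.delim(file.path(indir, "totals.tsv"))
groups <- factor(totals$group, levels = unique(totals$group))
peaks <- lapply(totals$sample, function(sm) {
  read_narrowpeak(file.path(indir, paste0(sm, ".narrowPeak")), sample = sm)
})

merged <- merge_peaks(peaks)
cat("Merged", sum(merged$n_constituents), "peak calls into",
    nrow(merged), "consensus regions\n")

# per-locus counts from the simulation stand in for BAM coverage extraction
chip <- read_count_table(file.path(indir, "chip_counts.tsv"))
input <- read_count_table(file.path(indir, "input_counts.tsv"))
locus <- vapply(merged$constituents,
                function(x) names(sort(table(sub("^[^_]*_", "", x)),
                                       decreasing = TRUE))[1], "")
chip_raw <- chip[locus, ]; input_raw <- input[locus, ]
rownames(chip_raw) <- rownames(input_raw) <- merged$peak_id

norm <- normalize_subtract(chip_raw, input_raw,
                           setNames(totals$chip_total, totals$sample),
                           setNames(totals$input_total, totals$sample),
                           merged$end - merged$start)
res <- differential_acetylation(norm$signal, groups)

classif <- data.frame(
  peak_id = merged$peak_id,
  proximity = classify_proximal_distal(merged, ann),
  classify_feature(merged, ann))

write_tsv(merged[, c("peak_id", "chrom", "start", "end", "summit",
                     "n_constituents")], "results/merged_peaks.tsv")
write_count_table(norm$signal, "results/peak_signal.tsv", id_col = "peak_id")
write_tsv(res, "results/chip_diff.tsv")
write_tsv(classif, "results/peak_classification.tsv")
write_tsv(data.frame(peak_id = merged$peak_id, locus = locus),
          "results/peak_locus_map.tsv")

cat("Differential peaks (p < 0.05, |log2FC| >= 1):",
    sum(res$direction != "ns"),
    "(", sum(res$direction == "hyper"), "hyper /",
    sum(res$direction == "hypo"), "hypo )\n")
cat("Proximal:", sum(classif$proximity == "proximal"),
    "| distal:", sum(classif$proximity == "distal"), "\n")
print(table(classif$label))
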