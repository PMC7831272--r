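#!/usr/bin/env Rscript
# Link differential H3K27ac peaks to candidate target genes: enumerate all
# genes with a TSS within 1 Mb of a differential summit, correlate peak
# signal with gene FPKM across the six samples, keep pairs with |r| > 0.8
# and p < 0.01, rank the top peak-associated genes per direction, and
# summarize how link frequency decays with distance.

library(acetylink)

ann <- parse_annotation("results/sim/annotation.gtf")
merged <- read.delim("results/merged_peaks.tsv")
chipres <- read.delim("results/chip_diff.tsv")
signal <- read_count_table("results/peak_signal.tsv")
fp <- read_count_table("results/rna_fpkm.tsv")

diff_peaks <- merged[chipres$direction != "ns", ]
pairs <- candidate_pairs(diff_peaks, ann)
pairs <- pairs[pairs$gene_id %in% rownames(fp), ]
cat("Candidate peak-gene pairs within 1 Mb:", nrow(pairs), "\n")

scored <- score_links(pairs, signal, fp)
links <- select_links(scored)
links$peak_direction <- chipres$direction[match(links$peak_id,
                                                chipres$feature)]
top <- top_peak_genes(links, chipres)
decay <- distance_decay(links)

write_tsv(links, "results/links.tsv")
write_tsv(decay, "results/link_distance_decay.tsv")
if (nrow(top$hyper) > 0) write_tsv(top$hyper, "results/top_genes_hyper.tsv")
if (nrow(top$hypo) > 0) write_tsv(top$hypo, "results/top_genes_hypo.tsv")

cat("Selected links (|r| > 0.8, p < 0.01):", nrow(links),
    "(", sum(links$sign == "positive"), "positive /",
    sum(links$sign == "negative"), "negative )\n")
if (nrow(links) > 0) {
  cat("Mean summit-TSS distance:", round(mean(links$distance) / 1e3, 1),
      "kb\n")
}

# recovery against the planted truth (peak ids mapped back to sim loci)
truth <- read.delim("results/sim/truth_links.tsv")
locus_map <- read.delim("results/peak_locus_map.tsv")
got <- paste(locus_map$locus[match(links$peak_id, locus_map$peak_id)],
             links$gene_id)
want <- paste(truth$peak_id, truth$gene_id)
cat("Planted links recovered:", sum(want %in% got), "of", nrow(truth), "\n")
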