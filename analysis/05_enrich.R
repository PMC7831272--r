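#!/usr/bin/env Rscript
# Enrichment analyses downstream of the differential peaks: PWM motif
# enrichment of differential-peak sequences against the non-differential
# background (the planted motif versus decoy motifs), and hypergeometric
# over-representation of the linked target genes in gene sets constructed
# around the planted link structure.

library(acetylink)

seqs <- read_fasta_seqs("results/sim/peak_sequences.fasta")
chipres <- read.delim("results/chip_diff.tsv")
locus_map <- read.delim("results/peak_locus_map.tsv")
pwms <- read_pwms(system.file("extdata", "pwms.txt", package = "acetylink"))

diff_loci <- locus_map$locus[match(chipres$feature[chipres$direction != "ns"],
                                   locus_map$peak_id)]
bg_loci <- setdiff(names(seqs), diff_loci)
motifs <- motif_enrichment_table(seqs[diff_loci], seqs[bg_loci], pwms)
write_tsv(motifs, "results/motif_enrichment.tsv")
cat("Motif enrichment in", length(diff_loci), "differential vs",
    length(bg_loci), "background sequences:\n")
print(motifs[, c("name", "overlap", "frac_targets", "p", "padj")])

# gene sets built around the simulation: the planted target genes versus
# size-matched random sets drawn from the expressed universe
universe <- rownames(read_count_table("results/rna_fpkm.tsv"))
truth <- read.delim("results/sim/truth_links.tsv")
set.seed(42)
sets <- c(list(planted_targets = truth$gene_id),
          lapply(1:9, function(i) sample(universe, length(truth$gene_id))))
names(sets)[-1] <- paste0("random_set_", 1:9)
write_gmt(sets, "results/gene_sets.gmt")

links <- read.delim("results/links.tsv")
query <- unique(links$gene_id)
ora <- geneset_enrichment(query, universe, read_gmt("results/gene_sets.gmt"))
write_tsv(ora, "results/geneset_enrichment.tsv")
cat("\nTop gene sets for the", length(query), "linked genes:\n")
print(head(ora[, c("name", "overlap", "set_size", "p", "padj")], 3))
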