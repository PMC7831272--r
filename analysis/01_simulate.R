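#!/usr/bin/env Rscript
# Generate the synthetic two-group (3 control vs 3 FLHS) liver study used by
# the downstream analysis scripts: toy genome annotation, per-sample H3K27ac
# peak calls, ChIP/input and RNA count tables with planted differential
# structure, planted enhancer-gene correlations, and motif-embedded peak
# sequences. Everything is a pure function of the seed.

library(acetylink)

seed <- 42
outdir <- "results/sim"

cfg <- sim_config(seed = seed)
study <- simulate_study(cfg, outdir = outdir)

cat("Simulated study written to", outdir, "\n")
cat("  genes:", nrow(study$annotation$genes),
    "| peak loci:", nrow(study$consensus),
    "| samples:", paste(study$samples, collapse = ", "), "\n")
cat("  planted differential peaks:", nrow(study$truth$peaks),
    "| planted DE genes:", nrow(study$truth$genes),
    "| planted links:", nrow(study$truth$links), "\n")
cat("  motif-bearing differential peaks:",
    length(study$truth$motif_peaks), "\n")
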