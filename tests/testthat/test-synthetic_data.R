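test_that("config validation rejects impossible settings", {
  expect_error(sim_config(planted_diff_fraction = 1.5), "fractions")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
  expect_error(sim_config(base_mean = 0), "base_mean")
  expect_error(sim_config(n_samples_per_group = 1), "2 samples")
})

test_that("simulated annotation is deterministic, bounded and non-overlapping", {
  cfg <- sim_config(seed = 42, n_chroms = 2, chrom_length = 5e6, n_genes = 30)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 30)
  expect_true(all(ann$genes$start >= 0))
  expect_true(all(ann$genes$end <= ann$chrom_sizes[ann$genes$chrom]))
  for (ch in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # byte-identical GTF on rerun with the same seed
  p1 <- tempfile(); p2 <- tempfile()
  write_gtf(simulate_annotation(cfg), p1)
  write_gtf(simulate_annotation(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
  # degenerate empty annotation is valid
  ann0 <- simulate_annotation(sim_config(n_genes = 0))
  expect_equal(nrow(ann0$genes), 0)
  # infeasible packing errors out with advice
  expect_error(simulate_annotation(sim_config(n_genes = 5000, n_chroms = 1,
                                              chrom_length = 1e5)),
               "chrom_length")
})

test_that("counts are NB with the planted effect and recorded library sizes", {
  cfg <- sim_config(seed = 7, nb_dispersion = 0.05, base_mean = 100,
                    base_mean_sdlog = 0)
  ids <- sprintf("g%05d", 1:500)
  lfc <- stats::setNames(rep(2, 500), ids)
  sim <- simulate_counts(cfg, ids, true_lfc = lfc)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_identical(sim$lib_sizes, colSums(sim$counts))
  # mean group-B/group-A ratio across planted features near 2^2 = 4
  ratio <- rowMeans(sim$counts[, 4:6]) / rowMeans(sim$counts[, 1:3])
  expect_gt(mean(ratio), 3.5)
  expect_lt(mean(ratio), 4.5)
  # determinism under the same seed
  sim2 <- simulate_counts(cfg, ids, true_lfc = lfc)
  expect_identical(sim$counts, sim2$counts)
  # no planted effects when the fraction is zero
  study0 <- suppressWarnings(
    simulate_study(sim_config(seed = 3, planted_diff_fraction = 0)))
  expect_equal(nrow(study0$truth$peaks), 0)
  expect_equal(nrow(study0$truth$genes), 0)
})

test_that("the full study is deterministic and truth ids are generated ids", {
  cfg <- sim_config(seed = 11)
  s1 <- suppressWarnings(simulate_study(cfg))
  s2 <- suppressWarnings(simulate_study(cfg))
  expect_identical(s1$rna_counts, s2$rna_counts)
  expect_identical(s1$chip_counts, s2$chip_counts)
  expect_identical(s1$sequences, s2$sequences)
  # referential integrity of the planted truth
  expect_true(all(s1$truth$peaks$peak_id %in% s1$consensus$peak_id))
  expect_true(all(s1$truth$genes$gene_id %in% rownames(s1$rna_counts)))
  expect_true(all(s1$truth$links$gene_id %in% rownames(s1$rna_counts)))
  expect_true(all(s1$truth$links$peak_id %in% s1$consensus$peak_id))
  # planted pairs always lie within the 1 Mb window
  expect_true(all(s1$truth$links$distance <= 1e6))
})

test_that("planted links reach the target correlation on average", {
  cfg <- link_study_config(seed = 3)
  study <- suppressWarnings(simulate_study(cfg))
  expect_gte(nrow(study$truth$links), 150)
  fp <- fpkm(study$rna_counts, study$gene_lengths[rownames(study$rna_counts)])
  rs <- vapply(seq_len(nrow(study$truth$links)), function(i) {
    cor(study$peak_signal[study$truth$links$peak_id[i], ],
        fp[study$truth$links$gene_id[i], ])
  }, 0)
  expect_gte(mean(rs), 0.9)
})

test_that("motif planting is guaranteed at rate 1 and absent at rate 0", {
  cfg <- sim_config(seed = 19, motif_plant_rate = 1)
  study <- suppressWarnings(simulate_study(cfg))
  diff_ids <- study$truth$peaks$peak_id
  hits <- has_motif(study$sequences[diff_ids], study$pwm)
  expect_true(all(hits))
  # rate 0: differential sequences behave like background
  cfg0 <- sim_config(seed = 19, motif_plant_rate = 0)
  study0 <- suppressWarnings(simulate_study(cfg0))
  expect_length(study0$truth$motif_peaks, 0)
  h_diff <- mean(has_motif(study0$sequences[study0$truth$peaks$peak_id],
                           study0$pwm))
  h_bg <- mean(has_motif(study0$sequences, study0$pwm))
  # both rates are tiny for the sharp default motif (binomial-error bound)
  expect_lt(h_diff, 0.2)
  expect_lt(h_bg, 0.1)
  # FASTA output is byte-identical across reruns
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta_seqs(suppressWarnings(simulate_study(cfg))$sequences, f1)
  write_fasta_seqs(suppressWarnings(simulate_study(cfg))$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
})
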