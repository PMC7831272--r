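# small in-code fixtures shared across tests

# two-exon gene on each strand plus a two-transcript gene, GTF 1-based
toy_gtf_lines <- function() {
  at <- function(g, t = NULL) {
    if (is.null(t)) sprintf('gene_id "%s";', g)
    else sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  }
  row <- function(chrom, feat, s, e, strand, attrs) {
    paste(chrom, "test", feat, s, e, ".", strand, ".", attrs, sep = "\t")
  }
  c(
    row("chr1", "gene", 100, 400, "+", at("gplus")),
    row("chr1", "transcript", 100, 400, "+", at("gplus", "tplus")),
    row("chr1", "exon", 100, 200, "+", at("gplus", "tplus")),
    row("chr1", "exon", 300, 400, "+", at("gplus", "tplus")),
    row("chr1", "gene", 5100, 5400, "-", at("gminus")),
    row("chr1", "transcript", 5100, 5400, "-", at("gminus", "tminus")),
    row("chr1", "exon", 5100, 5200, "-", at("gminus", "tminus")),
    row("chr1", "exon", 5300, 5400, "-", at("gminus", "tminus")),
    # two transcripts: exonic lengths 300 (9000..9300) vs 500 (9501..10400)
    row("chr2", "gene", 9000, 10400, "+", at("gtwo")),
    row("chr2", "transcript", 9000, 9300, "+", at("gtwo", "t_short")),
    row("chr2", "exon", 9000, 9299, "+", at("gtwo", "t_short")),
    row("chr2", "transcript", 9501, 10400, "+", at("gtwo", "t_long")),
    row("chr2", "exon", 9501, 10000, "+", at("gtwo", "t_long"))
  )
}

toy_annotation <- function() {
  path <- tempfile(fileext = ".gtf")
  writeLines(toy_gtf_lines(), path)
  parse_annotation(path, chrom_sizes = c(chr1 = 1e6, chr2 = 1e6))
}

toy_peak <- function(chrom, start, end, summit = NULL, id = "pk1",
                     score = 1, sample = "s1") {
  if (is.null(summit)) summit <- start + (end - start) %/% 2
  data.frame(peak_id = id, chrom = chrom, start = start, end = end,
             summit = summit, score = score, sample = sample,
             stringsAsFactors = FALSE)
}

random_peak_instance <- function(n, n_chrom = 2, span = 10000) {
  data.frame(
    peak_id = sprintf("p%03d", seq_len(n)),
    chrom = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
    summit = sample(span, n, replace = TRUE),
    score = stats::runif(n),
    stringsAsFactors = FALSE
  ) -> pk
  pk$start <- pmax(0, pk$summit - 250)
  pk$end <- pk$summit + 250
  pk$sample <- "s1"
  pk
}

# count-only simulation harness: planted two-group NB features
planted_counts <- function(n_features = 10000, n_planted = 500, lfc = 2,
                           alpha = 0.05, mean = 100, seed = 1) {
  cfg <- sim_config(seed = seed, nb_dispersion = alpha, base_mean = mean,
                    base_mean_sdlog = 0)
  ids <- sprintf("f%05d", seq_len(n_features))
  planted <- if (n_planted > 0) {
    stats::setNames(lfc * rep_len(c(1, -1), n_planted), ids[seq_len(n_planted)])
  } else NULL
  sim <- simulate_counts(cfg, ids, true_lfc = planted, stream = "rna")
  list(counts = sim$counts, planted = names(planted),
       true_lfc = planted, groups = sim_groups(cfg))
}

# study-scale configuration with enough planted links for recovery checks
link_study_config <- function(seed = 3) {
  sim_config(seed = seed, n_chroms = 25, chrom_length = 4e7, n_genes = 2000,
             n_peaks = 600, planted_diff_fraction = 0.5,
             planted_de_fraction = 0.05, planted_link_fraction = 0.7,
             target_link_r = 0.99, base_mean = 2000, base_mean_sdlog = 0.3)
}
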