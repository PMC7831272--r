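#' Synthetic study generator
#'
#' Seeded generator of a toy genome with annotation, H3K27ac peak calls,
#' ChIP/input and RNA-seq counts, planted differential structure, planted
#' peak-gene correlations, and motif-embedded peak sequences, emulating a
#' 2-group x 3-replicate liver study (control vs FLHS). Counts follow a
#' negative binomial with variance mu + alpha * mu^2 and a single
#' dispersion alpha per run; per-sample depth varies via lognormal size
#' factors. Every output is a pure function of the configuration, seed
#' included: one global seed feeds a derived sub-seed per stage so that,
#' e.g., enlarging the peak set does not perturb the RNA count draws.
#'
#' The generator deliberately isolates differential regulatory
#' neighborhoods: differential peaks are kept far apart (default 2.2 Mb)
#' so that each planted enhancer-gene pair has exactly one differential
#' peak within the 1 Mb linking window. Real genomes violate this (nearby
#' co-regulated peaks share the group effect, producing indirect
#' correlations), which is why planted-link recovery here measures the
#' linking machinery, not performance on real data.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' @param seed Global seed (integer).
#' @param n_chroms,chrom_length Genome shape (chromosomes x bp).
#' @param n_genes,n_peaks Total genes and consensus peak loci.
#' @param n_samples_per_group Replicates per group (default 3, as
#'   sequenced: three control and three case birds).
#' @param nb_dispersion NB dispersion alpha (variance mu + alpha mu^2).
#' @param base_mean Baseline expected count per feature.
#' @param base_mean_sdlog Lognormal spread of per-feature baselines
#'   (0 = all features share `base_mean`).
#' @param input_ratio Input (fragmentation) mean as a fraction of the ChIP
#'   mean; input has no group effect.
#' @param planted_diff_fraction Fraction of peak loci given a true group
#'   effect.
#' @param planted_de_fraction Fraction of genes given a true expression
#'   group effect (defaults to `planted_diff_fraction`). Kept small in
#'   large designs: because FPKM divides by the realized library size, a
#'   transcriptome dominated by one-sided fold changes would distort the
#'   abundance of every other gene.
#' @param planted_lfc Absolute log2 fold change of planted effects (signs
#'   alternate).
#' @param planted_link_fraction Fraction of differential peaks given a
#'   planted target gene within 1 Mb.
#' @param target_link_r Target Pearson correlation of planted pairs.
#' @param motif_plant_rate Fraction of differential-peak sequences carrying
#'   an embedded motif instance.
#' @param peak_width Width of simulated peaks (bp).
#' @param summit_jitter Per-sample summit jitter (bp, uniform, strictly
#'   below half the 1 kb merge threshold so merging recovers loci).
#' @param min_peak_sep Minimum spacing of consensus summits (bp).
#' @param diff_peak_sep Minimum spacing between differential peaks (bp).
#' @param size_factor_sdlog Lognormal sd of per-sample size factors.
#' @param total_reads Nominal total mapped reads per library before size
#'   factors.
#' @param pwm A [pwm()] to plant; `NULL` uses the built-in sharp 10-bp
#'   motif.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chroms = 5, chrom_length = 2e7,
                       n_genes = 80, n_peaks = 150, n_samples_per_group = 3,
                       nb_dispersion = 0.05, base_mean = 100,
                       base_mean_sdlog = 0.5, input_ratio = 0.5,
                       planted_diff_fraction = 0.15,
                       planted_de_fraction = NULL, planted_lfc = 2,
                       planted_link_fraction = 0.5, target_link_r = 0.99,
                       motif_plant_rate = 1, peak_width = 1000,
                       summit_jitter = 200, min_peak_sep = 3000,
                       diff_peak_sep = 2.2e6, size_factor_sdlog = 0.1,
                       total_reads = 2e7, pwm = NULL) {
  if (is.null(planted_de_fraction)) planted_de_fraction <- planted_diff_fraction
  fracs <- c(planted_diff_fraction, planted_de_fraction,
             planted_link_fraction, motif_plant_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (base_mean <= 0) stop("base_mean must be positive")
  if (n_samples_per_group < 2) stop("need at least 2 samples per group")
  if (abs(target_link_r) > 1) stop("target_link_r must lie in [-1, 1]")
  cfg <- as.list(environment())[names(formals(sim_config))]
  if (is.null(cfg$pwm)) cfg$pwm <- default_pwm()
  structure(cfg, class = "sim_config")
}

#' Built-in planted motif
#'
#' A sharp 10-bp motif (consensus ACGTCATGCA, probability 0.94 on the
#' consensus base). At the default 0.8 relative score threshold only
#' exact-consensus windows score as hits, so the background hit rate in
#' 1 kb random sequence is ~0.2% per sequence.
#'
#' @return A [pwm()] object named "planted".
#' @export
default_pwm <- function() {
  consensus <- c("A", "C", "G", "T", "C", "A", "T", "G", "C", "A")
  mat <- matrix(0.02, length(consensus), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(consensus)) mat[i, consensus[i]] <- 0.94
  pwm(mat, name = "planted")
}

# derived per-stage seed from the global seed (kept below 2^31)
sub_seed <- function(seed, tag) {
  tags <- c(annotation = 1, peaks = 2, chip = 3, input = 4, rna = 5,
            links = 6, sequences = 7, qpcr = 8)
  as.integer((as.numeric(seed) * 48271 + tags[[tag]] * 1000003) %% 2147483647)
}

#' Simulate a toy genome annotation
#'
#' Places non-overlapping genes with 2-6 exons each and random strand on
#' `n_chroms` chromosomes; deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A `genome_annotation`.
#' @export
simulate_annotation <- function(config) {
  set.seed(sub_seed(config$seed, "annotation"))
  n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  genes <- transcripts <- exons <- list()
  gi <- 0
  for (ci in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", ci)
    ng <- n_per[ci]
    if (ng == 0) next
    # draw gene structures first, then check packing
    structs <- lapply(seq_len(ng), function(i) {
      ne <- sample(2:6, 1)
      elen <- sample(150:400, ne, replace = TRUE)
      ilen <- if (ne > 1) sample(500:3000, ne - 1, replace = TRUE) else integer(0)
      starts <- cumsum(c(0, elen[-ne] + ilen))
      list(ne = ne, estart = starts, eend = starts + elen,
           span = starts[ne] + elen[ne])
    })
    spans <- vapply(structs, `[[`, 0, "span")
    slot <- max(spans) + config$min_peak_sep
    n_slots <- floor(config$chrom_length / slot)
    if (n_slots < ng) {
      stop("infeasible gene packing on ", chrom,
           ": increase chrom_length or reduce n_genes")
    }
    slots <- sort(sample(n_slots, ng))
    for (i in seq_len(ng)) {
      gi <- gi + 1
      st <- structs[[i]]
      gstart <- (slots[i] - 1) * slot +
        sample(0:(slot - st$span), 1)
      gid <- sprintf("gene%04d", gi)
      tid <- sprintf("tx%04d", gi)
      strand <- sample(c("+", "-"), 1)
      genes[[gi]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                                start = gstart, end = gstart + st$span,
                                stringsAsFactors = FALSE)
      transcripts[[gi]] <- data.frame(transcript_id = tid, gene_id = gid,
                                      chrom = chrom, strand = strand,
                                      start = gstart, end = gstart + st$span,
                                      stringsAsFactors = FALSE)
      exons[[gi]] <- data.frame(transcript_id = tid, gene_id = gid,
                                chrom = chrom, strand = strand,
                                start = gstart + st$estart,
                                end = gstart + st$eend,
                                stringsAsFactors = FALSE)
    }
  }
  chrom_sizes <- stats::setNames(rep(as.integer(config$chrom_length),
                                     config$n_chroms),
                                 paste0("chr", seq_len(config$n_chroms)))
  if (gi == 0) {
    return(structure(list(
      genes = data.frame(gene_id = character(0), chrom = character(0),
                         strand = character(0), start = integer(0),
                         end = integer(0)),
      transcripts = data.frame(transcript_id = character(0),
                               gene_id = character(0), chrom = character(0),
                               strand = character(0), start = integer(0),
                               end = integer(0)),
      exons = data.frame(transcript_id = character(0), gene_id = character(0),
                         chrom = character(0), strand = character(0),
                         start = integer(0), end = integer(0)),
      tss = stats::setNames(integer(0), character(0)),
      canonical = stats::setNames(character(0), character(0)),
      chrom_sizes = chrom_sizes), class = "genome_annotation"))
  }
  genes <- do.call(rbind, genes)
  transcripts <- do.call(rbind, transcripts)
  exons <- do.call(rbind, exons)
  canonical <- stats::setNames(transcripts$transcript_id, transcripts$gene_id)
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  tss <- stats::setNames(as.integer(tss), genes$gene_id)
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 tss = tss, canonical = canonical[genes$gene_id],
                 chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' Simulate consensus peak loci and per-sample peak calls
#'
#' Consensus summits are spaced at least `min_peak_sep` apart; each sample
#' sees every locus with its summit jittered by at most `summit_jitter` bp,
#' so per-sample summits of one locus always fall within the 1 kb merge
#' criterion while distinct loci never chain. A `planted_diff_fraction` of
#' loci receive a true group effect of +/- `planted_lfc` (alternating
#' sign), with differential loci spaced at least `diff_peak_sep` apart.
#'
#' @param config A [sim_config()].
#' @return List with `consensus` (data.frame `peak_id`, `chrom`, `start`,
#'   `end`, `summit`), `per_sample` (named list of narrowPeak-style
#'   data.frames), and `truth_peaks` (`peak_id`, `true_lfc` for planted
#'   differential loci).
#' @export
simulate_peaks <- function(config) {
  set.seed(sub_seed(config$seed, "peaks"))
  n_per <- diff(round(seq(0, config$n_peaks, length.out = config$n_chroms + 1)))
  w <- config$peak_width
  cons <- list()
  pi_ <- 0
  for (ci in seq_len(config$n_chroms)) {
    npk <- n_per[ci]
    if (npk == 0) next
    slot <- config$min_peak_sep
    n_slots <- floor((config$chrom_length - w) / slot)
    if (n_slots < npk) stop("infeasible peak packing: increase chrom_length")
    slots <- sort(sample(n_slots, npk))
    start <- (slots - 1) * slot
    cons[[ci]] <- data.frame(
      peak_id = sprintf("locus%05d", pi_ + seq_len(npk)),
      chrom = paste0("chr", ci), start = start, end = start + w,
      summit = start + w %/% 2L, stringsAsFactors = FALSE)
    pi_ <- pi_ + npk
  }
  consensus <- do.call(rbind, cons)
  rownames(consensus) <- NULL

  # differential loci: spaced >= diff_peak_sep, alternating effect sign
  n_diff <- round(config$planted_diff_fraction * nrow(consensus))
  chosen <- integer(0)
  for (i in sample(nrow(consensus))) {
    if (length(chosen) >= n_diff) break
    ok <- TRUE
    for (j in chosen) {
      if (consensus$chrom[i] == consensus$chrom[j] &&
          abs(consensus$summit[i] - consensus$summit[j]) < config$diff_peak_sep) {
        ok <- FALSE; break
      }
    }
    if (ok) chosen <- c(chosen, i)
  }
  if (length(chosen) < n_diff) {
    warning("placed ", length(chosen), " of ", n_diff,
            " differential loci under the spacing constraint")
  }
  chosen <- sort(chosen)
  truth_peaks <- data.frame(
    peak_id = consensus$peak_id[chosen],
    true_lfc = config$planted_lfc * rep_len(c(1, -1), length(chosen)),
    stringsAsFactors = FALSE)

  samples <- sample_ids(config)
  per_sample <- lapply(samples, function(sm) {
    jit <- sample(-config$summit_jitter:config$summit_jitter,
                  nrow(consensus), replace = TRUE)
    summit <- consensus$summit + jit
    start <- pmax(0L, summit - w %/% 2L)
    data.frame(peak_id = paste0(sm, "_", consensus$peak_id),
               chrom = consensus$chrom, start = start, end = start + w,
               summit = summit, score = round(stats::runif(nrow(consensus), 1, 100), 2),
               sample = sm, stringsAsFactors = FALSE)
  })
  names(per_sample) <- samples
  list(consensus = consensus, per_sample = per_sample,
       truth_peaks = truth_peaks)
}

sample_ids <- function(config) {
  n <- config$n_samples_per_group
  c(paste0("ctrl", seq_len(n)), paste0("flhs", seq_len(n)))
}

#' Group labels for the simulated design
#' @param config A [sim_config()].
#' @return Factor of "control"/"FLHS" per sample, control first.
#' @export
sim_groups <- function(config) {
  n <- config$n_samples_per_group
  factor(rep(c("control", "FLHS"), each = n), levels = c("control", "FLHS"))
}

#' Simulate an NB count table with planted effects
#'
#' Counts are NB(mean = s_j * q_i * 2^(lfc_i * group_j), dispersion alpha)
#' with lognormal per-sample size factors s_j; per-feature baselines q_i
#' are lognormal around `base_mean` (or all equal when
#' `base_mean_sdlog = 0`).
#'
#' @param config A [sim_config()].
#' @param ids Feature ids (rownames of the result).
#' @param true_lfc Named vector of planted log2 fold changes (features not
#'   named get 0); `group_effect = FALSE` ignores it (input libraries).
#' @param base_means Optional fixed per-feature baselines (overrides the
#'   lognormal draw); recycled.
#' @param group_effect Apply the planted group effect (default `TRUE`).
#' @param stream Seed stream tag (`"rna"`, `"chip"`, or `"input"`).
#' @return List: integer `counts` matrix (features x samples),
#'   `size_factors`, `base_means`, `totals` (nominal total mapped reads per
#'   library), and `lib_sizes` (column sums).
#' @export
simulate_counts <- function(config, ids, true_lfc = NULL, base_means = NULL,
                            group_effect = TRUE, stream = "rna") {
  set.seed(sub_seed(config$seed, stream))
  n_feat <- length(ids)
  n <- 2 * config$n_samples_per_group
  grp <- as.integer(sim_groups(config)) - 1L  # 0 = control, 1 = FLHS
  sf <- exp(stats::rnorm(n, 0, config$size_factor_sdlog))
  if (is.null(base_means)) {
    q <- config$base_mean *
      exp(stats::rnorm(n_feat, 0, config$base_mean_sdlog))
  } else {
    q <- rep_len(base_means, n_feat)
  }
  lfc <- rep(0, n_feat)
  names(lfc) <- ids
  if (!is.null(true_lfc) && group_effect) {
    lfc[names(true_lfc)] <- true_lfc
  }
  mu <- outer(q, sf) * 2^(outer(lfc, grp))
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  counts <- matrix(
    if (is.finite(size)) stats::rnbinom(n_feat * n, mu = mu, size = size)
    else stats::rpois(n_feat * n, lambda = mu),
    n_feat, n, dimnames = list(ids, sample_ids(config)))
  list(counts = counts, size_factors = stats::setNames(sf, sample_ids(config)),
       base_means = stats::setNames(q, ids),
       totals = stats::setNames(round(config$total_reads * sf),
                                sample_ids(config)),
       lib_sizes = colSums(counts))
}

#' Plant peak-gene correlations into an RNA count table
#'
#' For a fraction of differential peaks, the nearest gene with a TSS within
#' `window` bp has its counts rewritten so that its FPKM is an affine
#' function of the peak's normalized subtracted signal plus Gaussian noise
#' scaled to an expected Pearson correlation of `target_link_r`. Peaks
#' with no candidate gene in the window are skipped with a warning. Counts
#' are re-planted over a few fixed-point iterations so the correlation
#' holds against final column-sum library sizes.
#'
#' @param config A [sim_config()].
#' @param peak_signal Normalized subtracted signal matrix (consensus locus
#'   ids x samples).
#' @param annotation The simulated `genome_annotation`.
#' @param truth_peaks Planted differential loci from [simulate_peaks()].
#' @param rna_counts Integer RNA count matrix to modify.
#' @param gene_lengths Named exonic lengths (bp) used for the FPKM scale.
#' @param window Linking window (default 1e6 bp).
#' @param plant_mean_count Average count scale of planted genes (default
#'   300); the FPKM scale is derived from it so rounding to integer counts
#'   never degrades the planted correlation.
#' @return List: modified `counts` and `truth_links` data.frame
#'   (`peak_id`, `gene_id`, `distance`, `target_r`).
#' @export
simulate_links <- function(config, peak_signal, annotation, truth_peaks,
                           rna_counts, gene_lengths, window = 1e6,
                           plant_mean_count = 300) {
  set.seed(sub_seed(config$seed, "links"))
  n_links <- round(config$planted_link_fraction * nrow(truth_peaks))
  if (n_links == 0 || nrow(truth_peaks) == 0) {
    return(list(counts = rna_counts,
                truth_links = data.frame(peak_id = character(0),
                                         gene_id = character(0),
                                         distance = integer(0),
                                         target_r = numeric(0))))
  }
  g <- annotation$genes
  tss <- annotation$tss
  tss_chrom <- g$chrom[match(names(tss), g$gene_id)]
  cand_peaks <- sample(truth_peaks$peak_id)
  used_genes <- character(0)
  links <- list()
  targets <- list()
  loci <- attr(peak_signal, "loci")
  if (is.null(loci)) stop("peak_signal must carry a 'loci' attribute (see simulate_study)")
  for (pid in cand_peaks) {
    if (length(links) >= n_links) break
    ps <- loci[pid, ]
    same <- tss_chrom == ps$chrom & !(names(tss) %in% used_genes)
    d <- abs(tss[same] - ps$summit)
    ok <- d <= window
    if (!any(ok)) {
      warning("no candidate gene within ", window, " bp of ", pid, "; skipped")
      next
    }
    gid <- names(which.min(d[ok]))
    used_genes <- c(used_genes, gid)
    x <- peak_signal[pid, ]
    if (stats::sd(x) == 0) {
      warning("constant signal at ", pid, "; skipped")
      next
    }
    r <- config$target_link_r
    # FPKM scale putting the planted gene near plant_mean_count counts, so
    # integer rounding is negligible relative to the planted signal
    base_fpkm <- plant_mean_count /
      ((gene_lengths[gid] / 1e3) * (mean(colSums(rna_counts)) / 1e6))
    b <- sign(r + (r == 0)) * base_fpkm / max(mean(x), 1e-8)
    sigma <- if (abs(r) > 0) abs(b) * stats::sd(x) * sqrt(1 / r^2 - 1) else
      abs(b) * stats::sd(x) * 10
    noise <- stats::rnorm(length(x), 0, sigma)
    links[[length(links) + 1]] <- data.frame(
      peak_id = pid, gene_id = gid, distance = as.integer(min(d[ok])),
      target_r = r, stringsAsFactors = FALSE)
    targets[[gid]] <- b * x + noise +
      (if (r >= 0) 0 else 3 * base_fpkm)  # keep negative-r targets positive
  }
  truth_links <- if (length(links) > 0) do.call(rbind, links) else
    data.frame(peak_id = character(0), gene_id = character(0),
               distance = integer(0), target_r = numeric(0))
  # fixed point: planted counts depend on library sizes, which depend on counts
  counts <- rna_counts
  for (iter in 1:3) {
    lib <- colSums(counts)
    for (gid in names(targets)) {
      y <- pmax(targets[[gid]], 0)
      counts[gid, ] <- round(y * (gene_lengths[gid] / 1e3) * (lib / 1e6))
    }
  }
  list(counts = counts, truth_links = truth_links)
}

#' Simulate peak sequences with planted motif instances
#'
#' Each consensus locus gets a uniform-random sequence of its width; a
#' `motif_plant_rate` fraction of differential loci carry one embedded
#' motif instance sampled from the PWM, re-sampled until it scores at or
#' above the scanner's threshold (so a plant rate of 1 guarantees at least
#' one hit per differential sequence).
#'
#' @param config A [sim_config()].
#' @param consensus Consensus locus data.frame from [simulate_peaks()].
#' @param truth_peaks Planted differential loci.
#' @param rel_threshold Scan threshold used for instance acceptance
#'   (default 0.8).
#' @return List: named character `seqs`, and `motif_peaks` (locus ids with
#'   an embedded instance).
#' @export
simulate_sequences <- function(config, consensus, truth_peaks,
                               rel_threshold = 0.8) {
  set.seed(sub_seed(config$seed, "sequences"))
  m <- config$pwm
  L <- nrow(m$mat)
  if (L > min(consensus$end - consensus$start)) {
    stop("PWM longer than the shortest peak")
  }
  S <- log2(m$mat / rep(m$background, each = L))
  max_score <- sum(apply(S, 1, max))
  bases <- c("A", "C", "G", "T")
  draw_instance <- function() {
    for (try in 1:50) {
      idx <- vapply(seq_len(L), function(i) sample(4, 1, prob = m$mat[i, ]), 1L)
      if (sum(S[cbind(seq_len(L), idx)]) >= rel_threshold * max_score) {
        return(paste(bases[idx], collapse = ""))
      }
    }
    paste(bases[apply(m$mat, 1, which.max)], collapse = "")  # consensus
  }
  n <- nrow(consensus)
  widths <- consensus$end - consensus$start
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(bases, widths[i], replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- consensus$peak_id
  plant <- truth_peaks$peak_id[
    stats::runif(nrow(truth_peaks)) < config$motif_plant_rate]
  for (pid in plant) {
    wlen <- nchar(seqs[pid])
    pos <- sample(wlen - L + 1, 1)
    inst <- draw_instance()
    substr(seqs[pid], pos, pos + L - 1) <- inst
  }
  list(seqs = seqs, motif_peaks = plant)
}

#' Simulate the full study
#'
#' Runs all sub-generators in order (annotation, peaks, ChIP/input counts,
#' RNA counts, link planting, sequences) and optionally writes the file
#' bundle (GTF, per-sample narrowPeak, count TSVs, truth TSV, FASTA, and a
#' key=value config record).
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory for the file bundle.
#' @return List with the annotation, peak sets, count matrices and totals,
#'   normalized peak signal, gene lengths, group labels, sequences, the
#'   planted PWM, and a `truth` list (`peaks`, `genes`, `links`,
#'   `motif_peaks`).
#' @export
simulate_study <- function(config, outdir = NULL) {
  annotation <- simulate_annotation(config)
  pk <- simulate_peaks(config)
  loci <- pk$consensus

  chip_lfc <- stats::setNames(pk$truth_peaks$true_lfc, pk$truth_peaks$peak_id)
  chip <- simulate_counts(config, loci$peak_id, chip_lfc, stream = "chip")
  input <- simulate_counts(config, loci$peak_id,
                           base_means = chip$base_means * config$input_ratio,
                           group_effect = FALSE, stream = "input")
  norm <- normalize_subtract(chip$counts, input$counts, chip$totals,
                             input$totals, loci$end - loci$start)
  signal <- norm$signal
  attr(signal, "loci") <- loci[match(rownames(signal), loci$peak_id), ]
  rownames(attr(signal, "loci")) <- attr(signal, "loci")$peak_id

  # planted DE genes, kept away from differential loci so that expression
  # group effects cannot masquerade as peak-gene links
  set.seed(sub_seed(config$seed, "rna"))
  g <- annotation$genes
  n_de <- round(config$planted_de_fraction * nrow(g))
  diff_loci <- loci[loci$peak_id %in% pk$truth_peaks$peak_id, ]
  near_diff <- vapply(seq_len(nrow(g)), function(i) {
    sel <- diff_loci$chrom == g$chrom[i]
    any(abs(diff_loci$summit[sel] - annotation$tss[g$gene_id[i]]) <= 1.1e6)
  }, TRUE)
  eligible <- g$gene_id[!near_diff]
  de_genes <- sample(eligible, min(n_de, length(eligible)))
  gene_lfc <- stats::setNames(
    config$planted_lfc * rep_len(c(1, -1), length(de_genes)), de_genes)
  rna <- simulate_counts(config, g$gene_id, gene_lfc, stream = "rna")

  exlen <- tapply(annotation$exons$end - annotation$exons$start,
                  annotation$exons$gene_id, sum)
  gene_lengths <- stats::setNames(as.numeric(exlen[g$gene_id]), g$gene_id)

  lk <- simulate_links(config, signal, annotation, pk$truth_peaks,
                       rna$counts, gene_lengths)
  sq <- simulate_sequences(config, loci, pk$truth_peaks)

  study <- list(
    config = config, annotation = annotation, peaks = pk$per_sample,
    consensus = loci, chip_counts = chip$counts, input_counts = input$counts,
    chip_totals = chip$totals, input_totals = input$totals,
    peak_signal = signal, rna_counts = lk$counts,
    gene_lengths = gene_lengths, groups = sim_groups(config),
    samples = sample_ids(config), sequences = sq$seqs, pwm = config$pwm,
    truth = list(peaks = pk$truth_peaks,
                 genes = data.frame(gene_id = de_genes,
                                    true_lfc = unname(gene_lfc),
                                    stringsAsFactors = FALSE),
                 links = lk$truth_links, motif_peaks = sq$motif_peaks))
  if (!is.null(outdir)) write_study(study, outdir)
  study
}

write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(study$annotation, file.path(outdir, "annotation.gtf"))
  for (sm in names(study$peaks)) {
    write_narrowpeak(study$peaks[[sm]],
                     file.path(outdir, paste0(sm, ".narrowPeak")))
  }
  write_count_table(study$rna_counts, file.path(outdir, "rna_counts.tsv"),
                    id_col = "gene_id")
  write_count_table(study$chip_counts, file.path(outdir, "chip_counts.tsv"),
                    id_col = "peak_id")
  write_count_table(study$input_counts, file.path(outdir, "input_counts.tsv"),
                    id_col = "peak_id")
  totals <- data.frame(sample = study$samples,
                       chip_total = unname(study$chip_totals[study$samples]),
                       input_total = unname(study$input_totals[study$samples]),
                       group = as.character(study$groups))
  write_tsv(totals, file.path(outdir, "totals.tsv"))
  write_tsv(study$truth$peaks, file.path(outdir, "truth_peaks.tsv"))
  write_tsv(study$truth$genes, file.path(outdir, "truth_genes.tsv"))
  write_tsv(study$truth$links, file.path(outdir, "truth_links.tsv"))
  write_fasta_seqs(study$sequences, file.path(outdir, "peak_sequences.fasta"))
  cfg <- study$config
  keys <- setdiff(names(cfg), "pwm")
  writeLines(paste0(keys, "=", vapply(cfg[keys], format, "")),
             file.path(outdir, "sim_config.txt"))
  invisible(outdir)
}
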