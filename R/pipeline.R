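#' Pipeline orchestration
#'
#' Runs every stage in order from a single configuration — expression
#' filtering and differential expression, peak merging, signal
#' quantification and differential acetylation, peak-gene linking, motif
#' and gene-set enrichment — and writes each stage's table plus a summary
#' and a run manifest to the output directory. Defaults are the study
#' thresholds: 1 kb summit merge, 1 kb TSS proximity, 1 Mb linking window,
#' r > 0.8 and p < 0.01 links, DE padj <= 0.05, peak raw p < 0.05,
#' |log2FC| >= 1, top-100 gene lists.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param sim A [sim_config()] to self-generate inputs, or `NULL` to read
#'   from `input_dir` (a bundle as written by [simulate_study()]).
#' @param input_dir Directory of input files when `sim` is `NULL`.
#' @param outdir Output directory.
#' @param group Named vector mapping sample id to group label; `NULL`
#'   derives it from the simulation design or the bundle's totals table.
#' @param merge_dist Summit merge threshold, bp.
#' @param proximal_bp TSS proximity threshold, bp.
#' @param link_window Linking window, bp.
#' @param link_r,link_p Link selection thresholds.
#' @param de_padj,peak_p,lfc_threshold Differential thresholds.
#' @param top_k Genes per direction in the top lists.
#' @param seed Seed recorded in the manifest (the generator draws from
#'   `sim$seed`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL, outdir = tempfile("acetylink_run_"),
                            group = NULL, merge_dist = 1000, proximal_bp = 1000,
                            link_window = 1e6, link_r = 0.8, link_p = 0.01,
                            de_padj = 0.05, peak_p = 0.05, lfc_threshold = 1,
                            top_k = 100, seed = 1) {
  thr <- c(merge_dist, proximal_bp, link_window, link_r, link_p, de_padj,
           peak_p, lfc_threshold, top_k)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  if (is.null(sim) && is.null(input_dir)) {
    stop("either a simulation config or an input directory is required")
  }
  structure(as.list(environment())[c("sim", "input_dir", "outdir", "group",
                                     "merge_dist", "proximal_bp", "link_window",
                                     "link_r", "link_p", "de_padj", "peak_p",
                                     "lfc_threshold", "top_k", "seed")],
            class = "pipeline_config")
}

load_study_bundle <- function(input_dir) {
  annotation <- parse_annotation(file.path(input_dir, "annotation.gtf"))
  totals <- utils::read.table(file.path(input_dir, "totals.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  samples <- totals$sample
  peaks <- lapply(samples, function(sm) {
    read_narrowpeak(file.path(input_dir, paste0(sm, ".narrowPeak")), sample = sm)
  })
  names(peaks) <- samples
  fa <- file.path(input_dir, "peak_sequences.fasta")
  exlen <- tapply(annotation$exons$end - annotation$exons$start,
                  annotation$exons$gene_id, sum)
  list(annotation = annotation, peaks = peaks,
       rna_counts = read_count_table(file.path(input_dir, "rna_counts.tsv")),
       chip_counts = read_count_table(file.path(input_dir, "chip_counts.tsv")),
       input_counts = read_count_table(file.path(input_dir, "input_counts.tsv")),
       chip_totals = stats::setNames(totals$chip_total, samples),
       input_totals = stats::setNames(totals$input_total, samples),
       groups = factor(totals$group, levels = unique(totals$group)),
       samples = samples,
       gene_lengths = stats::setNames(as.numeric(exlen), names(exlen)),
       sequences = if (file.exists(fa)) read_fasta_seqs(fa) else NULL,
       pwm = NULL, truth = NULL)
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] %s (%.2fs)", format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full pipeline
#'
#' Stages: low-expression filter -> differential expression -> peak merge
#' -> quantification/normalization -> differential acetylation -> feature
#' classification -> candidate pairs -> link scoring and selection -> top
#' gene lists -> distance decay -> motif enrichment (when sequences and a
#' PWM are available). Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param pwms Optional list of [pwm()] objects for motif enrichment; when
#'   the study is simulated the planted PWM is appended.
#' @param gene_sets Optional named list of gene sets for ORA of the top
#'   linked genes.
#' @return Invisible list with every stage result and the summary.
#' @export
run_pipeline <- function(config, pwms = NULL, gene_sets = NULL) {
  t0 <- as.numeric(Sys.time())
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  study <- run_stage("inputs", {
    if (!is.null(config$sim)) simulate_study(config$sim)
    else load_study_bundle(config$input_dir)
  })
  if (!is.null(config$group)) {
    miss <- setdiff(study$samples, names(config$group))
    if (length(miss) > 0) {
      stop("config error: no group label for sample(s) ",
           paste(miss, collapse = ", "))
    }
    study$groups <- factor(config$group[study$samples],
                           levels = unique(config$group[study$samples]))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage_msg("inputs ready", t0)

  # RNA: filter, DE, FPKM
  de <- run_stage("rnaseq_diff", {
    filtered <- filter_low_expression(study$rna_counts)
    res <- nb_wald_test(filtered, study$groups,
                        params = nb_params(padj_threshold = config$de_padj,
                                           lfc_threshold = config$lfc_threshold,
                                           use_adjusted = TRUE))
    fp <- fpkm(filtered, study$gene_lengths[rownames(filtered)])
    list(filtered = filtered, res = res, fpkm = fp)
  })
  write_tsv(de$res, file.path(config$outdir, "rnaseq_diff.tsv"))
  stage_msg("differential expression", t0)

  # ChIP: merge, quantify (counts precomputed per locus in the bundle),
  # normalize, differential acetylation
  chip <- run_stage("chip_quant", {
    merged <- merge_peaks(study$peaks, summit_dist = config$merge_dist)
    # map merged peaks to bundle loci via constituent majority
    locus_of <- function(constituents) {
      ids <- sub("^[^_]*_", "", constituents)
      names(sort(table(ids), decreasing = TRUE))[1]
    }
    merged$locus <- vapply(merged$constituents, locus_of, "")
    chip_raw <- study$chip_counts[merged$locus, , drop = FALSE]
    input_raw <- study$input_counts[merged$locus, , drop = FALSE]
    rownames(chip_raw) <- rownames(input_raw) <- merged$peak_id
    norm <- normalize_subtract(chip_raw, input_raw, study$chip_totals,
                               study$input_totals, merged$end - merged$start)
    res <- differential_acetylation(
      norm$signal, study$groups,
      params = nb_params(padj_threshold = config$peak_p,
                         lfc_threshold = config$lfc_threshold,
                         use_adjusted = FALSE))
    list(merged = merged, signal = norm$signal, res = res)
  })
  write_tsv(chip$merged[, c("peak_id", "chrom", "start", "end", "summit",
                            "n_constituents", "locus")],
            file.path(config$outdir, "merged_peaks.tsv"))
  write_tsv(chip$res, file.path(config$outdir, "chip_diff.tsv"))
  stage_msg("differential acetylation", t0)

  classif <- run_stage("genome_model", {
    data.frame(peak_id = chip$merged$peak_id,
               proximity = classify_proximal_distal(chip$merged, study$annotation,
                                                    config$proximal_bp),
               classify_feature(chip$merged, study$annotation,
                                config$proximal_bp),
               stringsAsFactors = FALSE)
  })
  write_tsv(classif, file.path(config$outdir, "peak_classification.tsv"))
  stage_msg("peak classification", t0)

  links <- run_stage("linking", {
    diff_peaks <- chip$merged[chip$res$direction != "ns", , drop = FALSE]
    pairs <- candidate_pairs(diff_peaks, study$annotation, config$link_window)
    pairs <- pairs[pairs$gene_id %in% rownames(de$fpkm), , drop = FALSE]
    scored <- score_links(pairs, chip$signal, de$fpkm)
    sel <- select_links(scored, config$link_r, config$link_p)
    sel$peak_direction <- chip$res$direction[match(sel$peak_id, chip$res$feature)]
    top <- top_peak_genes(sel, chip$res, config$top_k)
    decay <- distance_decay(sel, bin_width = 1e5, max_dist = config$link_window)
    list(pairs = pairs, selected = sel, top = top, decay = decay)
  })
  write_tsv(links$selected, file.path(config$outdir, "links.tsv"))
  write_tsv(links$decay, file.path(config$outdir, "link_distance_decay.tsv"))
  if (nrow(links$top$hyper) > 0) {
    write_tsv(links$top$hyper, file.path(config$outdir, "top_genes_hyper.tsv"))
  }
  if (nrow(links$top$hypo) > 0) {
    write_tsv(links$top$hypo, file.path(config$outdir, "top_genes_hypo.tsv"))
  }
  stage_msg("peak-gene linking", t0)

  motif <- NULL
  if (!is.null(study$sequences)) {
    all_pwms <- pwms
    if (!is.null(study$pwm)) all_pwms <- c(all_pwms, list(study$pwm))
    if (length(all_pwms) > 0) {
      motif <- run_stage("motif_enrichment", {
        diff_ids <- chip$merged$locus[chip$res$direction != "ns"]
        bg_ids <- setdiff(names(study$sequences), diff_ids)
        motif_enrichment_table(study$sequences[diff_ids],
                               study$sequences[bg_ids], all_pwms)
      })
      write_tsv(motif, file.path(config$outdir, "motif_enrichment.tsv"))
      stage_msg("motif enrichment", t0)
    }
  }

  ora <- NULL
  if (!is.null(gene_sets)) {
    ora <- run_stage("geneset_enrichment", {
      query <- unique(c(links$top$hyper$gene_id, links$top$hypo$gene_id))
      geneset_enrichment(query, rownames(de$filtered), gene_sets)
    })
    write_tsv(ora, file.path(config$outdir, "geneset_enrichment.tsv"))
    stage_msg("gene-set enrichment", t0)
  }

  summary <- data.frame(
    metric = c("n_genes_tested", "n_deg", "n_deg_up", "n_deg_down",
               "n_merged_peaks", "n_diff_peaks", "n_hyper", "n_hypo",
               "n_links", "n_links_positive", "n_links_negative",
               "mean_link_distance_bp"),
    value = c(nrow(de$res),
              sum(de$res$direction != "ns"),
              sum(de$res$direction == "up"),
              sum(de$res$direction == "down"),
              nrow(chip$merged),
              sum(chip$res$direction != "ns"),
              sum(chip$res$direction == "hyper"),
              sum(chip$res$direction == "hypo"),
              nrow(links$selected),
              sum(links$selected$sign == "positive"),
              sum(links$selected$sign == "negative"),
              if (nrow(links$selected) > 0) mean(links$selected$distance) else NA))
  write_tsv(summary, file.path(config$outdir, "summary.tsv"))

  manifest <- list(
    package = "acetylink",
    version = as.character(utils::packageVersion("acetylink")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = sum(utf8ToInt(paste(
      vapply(config[!vapply(config, is.null, TRUE)],
             function(x) paste(format(x), collapse = ","), ""),
      collapse = ";"))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE)
  stage_msg("done", t0)
  invisible(list(config = config, study = study, de = de, chip = chip,
                 classification = classif, links = links, motif = motif,
                 ora = ora, summary = summary))
}
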