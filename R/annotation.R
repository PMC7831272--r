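#' Genome annotation model
#'
#' Parses an Ensembl-dialect GTF into an in-memory annotation holding genes,
#' transcripts, exons, and per-gene transcription start sites (TSS), and
#' classifies peaks relative to those features. All coordinates are stored
#' 0-based half-open; GTF is read and written 1-based inclusive.
#'
#' The TSS of a gene is taken from its canonical transcript, defined as the
#' transcript with the greatest summed exon length (ties broken by
#' lexicographically smallest transcript id). On the + strand the TSS is the
#' transcript's 5'-most base; on the - strand it is the last base of the
#' transcript interval.
#'
#' @name genome-annotation
NULL

gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0(key, '[ =]+"([^"]+)"'), attr))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Parse a GTF annotation
#'
#' Accepts gene/transcript/exon features; transcripts and genes absent as
#' explicit records are derived from exon extents. Coordinates are converted
#' from 1-based inclusive to 0-based half-open.
#'
#' @param gtf_path Path to a GTF file (attributes must carry `gene_id`, and
#'   `transcript_id` on transcript/exon records).
#' @param chrom_sizes Optional named vector of chromosome lengths, or a path
#'   to a two-column TSV. When absent, lengths are inferred as the maximum
#'   annotated end per chromosome.
#' @return An object of class `genome_annotation`: a list with `genes`,
#'   `transcripts`, `exons` data.frames, named vectors `tss` and
#'   `canonical` (gene id -> canonical transcript id), and `chrom_sizes`.
#' @export
parse_annotation <- function(gtf_path, chrom_sizes = NULL) {
  lines <- readLines(gtf_path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    bad <- idx[which(nf != 9)[1]]
    stop("malformed GTF line ", bad, " in ", gtf_path, ": expected 9 tab-separated fields, got ",
         nf[which(nf != 9)[1]])
  }
  feat <- vapply(fields, `[[`, "", 3)
  sel <- feat %in% c("gene", "transcript", "exon")
  fields <- fields[sel]
  feat <- feat[sel]
  chrom <- vapply(fields, `[[`, "", 1)
  start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5)))
  strand <- vapply(fields, `[[`, "", 7)
  attr <- vapply(fields, `[[`, "", 9)
  if (anyNA(start1) || anyNA(end1)) {
    bad <- which(is.na(start1) | is.na(end1))[1]
    stop("malformed GTF line ", idx[sel][bad], ": non-numeric coordinates")
  }
  gene_id <- gtf_attr(attr, "gene_id")
  tx_id <- gtf_attr(attr, "transcript_id")
  if (anyNA(gene_id)) stop("GTF record without gene_id attribute (line ",
                           idx[sel][which(is.na(gene_id))[1]], ")")
  rec <- data.frame(feat = feat, chrom = chrom, start = start1 - 1L, end = end1,
                    strand = strand, gene_id = gene_id, tx_id = tx_id,
                    stringsAsFactors = FALSE)

  ex <- rec[rec$feat == "exon", ]
  if (any(is.na(ex$tx_id))) stop("exon record without transcript_id attribute")
  ex <- ex[order(ex$tx_id, ex$start), ]
  exons <- data.frame(transcript_id = ex$tx_id, gene_id = ex$gene_id,
                      chrom = ex$chrom, strand = ex$strand,
                      start = ex$start, end = ex$end, stringsAsFactors = FALSE)

  # transcripts: explicit records, else derived from exon extents
  txr <- rec[rec$feat == "transcript", ]
  if (nrow(txr) > 0) {
    transcripts <- data.frame(transcript_id = txr$tx_id, gene_id = txr$gene_id,
                              chrom = txr$chrom, strand = txr$strand,
                              start = txr$start, end = txr$end,
                              stringsAsFactors = FALSE)
  } else {
    sp <- split(exons, exons$transcript_id)
    transcripts <- do.call(rbind, lapply(sp, function(e) {
      data.frame(transcript_id = e$transcript_id[1], gene_id = e$gene_id[1],
                 chrom = e$chrom[1], strand = e$strand[1],
                 start = min(e$start), end = max(e$end),
                 stringsAsFactors = FALSE)
    }))
  }
  transcripts <- transcripts[order(transcripts$transcript_id), ]
  rownames(transcripts) <- NULL

  gr <- rec[rec$feat == "gene", ]
  if (nrow(gr) > 0) {
    genes <- data.frame(gene_id = gr$gene_id, chrom = gr$chrom,
                        strand = gr$strand, start = gr$start, end = gr$end,
                        stringsAsFactors = FALSE)
  } else {
    sp <- split(transcripts, transcripts$gene_id)
    genes <- do.call(rbind, lapply(sp, function(tx) {
      data.frame(gene_id = tx$gene_id[1], chrom = tx$chrom[1],
                 strand = tx$strand[1], start = min(tx$start), end = max(tx$end),
                 stringsAsFactors = FALSE)
    }))
  }
  genes <- genes[order(genes$gene_id), ]
  rownames(genes) <- NULL

  # validate exon structure per transcript
  for (tid in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tid, ]
    tx <- transcripts[transcripts$transcript_id == tid, ]
    if (nrow(tx) == 0) stop("exon references unknown transcript ", tid)
    if (any(e$start < tx$start) || any(e$end > tx$end)) {
      stop("validation error: exon outside transcript bounds for ", tid)
    }
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("validation error: overlapping exons in transcript ", tid)
    }
  }

  # canonical transcript per gene: max summed exon length, ties -> smallest id
  exlen <- tapply(exons$end - exons$start, exons$transcript_id, sum)
  canonical <- vapply(split(transcripts, transcripts$gene_id), function(tx) {
    len <- exlen[tx$transcript_id]
    len[is.na(len)] <- tx$end - tx$start  # transcript without exon records
    cand <- tx$transcript_id[len == max(len)]
    sort(cand)[1]
  }, "")

  ctx <- transcripts[match(canonical, transcripts$transcript_id), ]
  tss <- ifelse(ctx$strand == "-", ctx$end - 1L, ctx$start)
  names(tss) <- names(canonical)

  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  if (is.null(chrom_sizes)) {
    if (nrow(genes) > 0) {
      chrom_sizes <- tapply(genes$end, genes$chrom, max)
      chrom_sizes <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
    } else {
      chrom_sizes <- integer(0)
    }
  }
  bad <- genes$end > chrom_sizes[genes$chrom]
  if (any(bad, na.rm = TRUE)) {
    stop("gene ", genes$gene_id[which(bad)[1]], " extends beyond its chromosome length")
  }

  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 tss = tss, canonical = canonical, chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts on", length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

#' Write an annotation back to GTF
#'
#' Emits gene, transcript and exon records (1-based inclusive) with
#' `gene_id`/`transcript_id` attributes. Re-parsing the written file yields
#' identical TSS positions.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @export
write_gtf <- function(annotation, path) {
  fmt <- function(chrom, src, feat, start, end, strand, attrs) {
    paste(chrom, src, feat, start + 1L, end, ".", strand, ".", attrs, sep = "\t")
  }
  g <- annotation$genes
  tx <- annotation$transcripts
  ex <- annotation$exons
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines, fmt(g$chrom[i], "acetylink", "gene", g$start[i], g$end[i],
                          g$strand[i], sprintf('gene_id "%s";', gid)))
    txi <- tx[tx$gene_id == gid, ]
    for (j in seq_len(nrow(txi))) {
      tid <- txi$transcript_id[j]
      at <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      lines <- c(lines, fmt(txi$chrom[j], "acetylink", "transcript",
                            txi$start[j], txi$end[j], txi$strand[j], at))
      exi <- ex[ex$transcript_id == tid, ]
      exi <- exi[order(exi$start), ]
      for (k in seq_len(nrow(exi))) {
        lines <- c(lines, fmt(exi$chrom[k], "acetylink", "exon",
                              exi$start[k], exi$end[k], exi$strand[k], at))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# distance from a point to an interval [start, end): 0 if the point lies on
# a covered base, else distance to the nearest covered base
point_interval_distance <- function(pos, start, end) {
  ifelse(pos >= start & pos < end, 0L,
         pmin(abs(pos - start), abs(pos - (end - 1L))))
}

#' Classify peaks as TSS-proximal or distal
#'
#' A peak is proximal when a TSS lies inside the peak or within
#' `threshold_bp` of a peak boundary (a distance of exactly `threshold_bp`
#' counts as proximal: "within 1 kb" is inclusive, distal requires over
#' 1 kb). Peaks on chromosomes with no annotated gene are distal.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`.
#' @param annotation A `genome_annotation`.
#' @param threshold_bp Proximity threshold in bp (default 1000).
#' @return Character vector, one of `"proximal"`/`"distal"` per peak.
#' @export
classify_proximal_distal <- function(peaks, annotation, threshold_bp = 1000) {
  tss_by_chrom <- split(unname(annotation$tss),
                        annotation$genes$chrom[match(names(annotation$tss),
                                                     annotation$genes$gene_id)])
  vapply(seq_len(nrow(peaks)), function(i) {
    tss <- tss_by_chrom[[peaks$chrom[i]]]
    if (is.null(tss) || length(tss) == 0) return("distal")
    d <- point_interval_distance(tss, peaks$start[i], peaks$end[i])
    if (min(d) <= threshold_bp) "proximal" else "distal"
  }, "")
}

#' Intron ordinal of a position within a transcript
#'
#' Returns the 1-based index of the intron containing `position`, counted
#' from the TSS side (left-to-right on +, right-to-left on -), or `NA` when
#' the position is exonic or outside the transcript. Single-exon transcripts
#' have no introns.
#'
#' @param position 0-based bp position.
#' @param exon_starts,exon_ends Ordered exon intervals (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @return Integer ordinal or `NA`.
#' @export
intron_ordinal <- function(position, exon_starts, exon_ends, strand = "+") {
  n <- length(exon_starts)
  if (n < 2) return(NA_integer_)
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]; exon_ends <- exon_ends[o]
  for (k in seq_len(n - 1)) {
    if (position >= exon_ends[k] && position < exon_starts[k + 1]) {
      return(if (strand == "-") (n - 1L) - k + 1L else as.integer(k))
    }
  }
  NA_integer_
}

#' Classify peak summits against genomic features
#'
#' Assigns each peak one label by its summit position with priority
#' promoter-TSS > exon > intron > intergenic. "promoter-TSS" means the
#' summit lies within `promoter_bp` of a TSS. Exon/intron containment is
#' resolved against each gene's canonical transcript; intronic summits also
#' carry the strand-aware 1-based intron ordinal.
#'
#' @param peaks data.frame with `chrom` and `summit` columns.
#' @param annotation A `genome_annotation`.
#' @param promoter_bp Promoter window around the TSS (default 1000).
#' @return data.frame with `label` and `intron_ordinal` columns.
#' @export
classify_feature <- function(peaks, annotation, promoter_bp = 1000) {
  g <- annotation$genes
  tss_chrom <- g$chrom[match(names(annotation$tss), g$gene_id)]
  can <- annotation$canonical
  tx <- annotation$transcripts
  ex <- annotation$exons
  out_label <- character(nrow(peaks))
  out_ord <- rep(NA_integer_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$summit[i]; ch <- peaks$chrom[i]
    tss <- annotation$tss[tss_chrom == ch]
    if (length(tss) > 0 && min(abs(tss - s)) <= promoter_bp) {
      out_label[i] <- "promoter-TSS"
      next
    }
    # genes whose canonical transcript contains the summit
    ctx <- tx[match(can, tx$transcript_id), ]
    hit <- which(ctx$chrom == ch & ctx$start <= s & s < ctx$end)
    if (length(hit) == 0) {
      out_label[i] <- "intergenic"
      next
    }
    lab <- "intron"; ord <- NA_integer_
    for (h in hit) {
      e <- ex[ex$transcript_id == ctx$transcript_id[h], ]
      if (any(e$start <= s & s < e$end)) { lab <- "exon"; ord <- NA_integer_; break }
      oo <- intron_ordinal(s, e$start, e$end, ctx$strand[h])
      if (!is.na(oo) && is.na(ord)) ord <- oo
    }
    if (lab == "intron" && is.na(ord)) lab <- "intergenic"  # between transcripts' exons? not intronic
    out_label[i] <- lab
    out_ord[i] <- if (lab == "intron") ord else NA_integer_
  }
  data.frame(label = out_label, intron_ordinal = out_ord,
             stringsAsFactors = FALSE)
}

#' Summit-to-TSS distance
#'
#' @param summit Peak summit position (bp).
#' @param tss Gene TSS position (bp).
#' @param peak_chrom,gene_chrom Chromosome names; must match.
#' @return Absolute distance in bp.
#' @export
peak_gene_distance <- function(summit, tss, peak_chrom = NULL, gene_chrom = NULL) {
  if (!is.null(peak_chrom) && !is.null(gene_chrom) &&
      any(peak_chrom != gene_chrom)) {
    stop("peak and gene on different chromosomes: distance undefined")
  }
  abs(summit - tss)
}
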