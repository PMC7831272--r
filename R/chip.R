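#' ChIP-seq peak merging, signal quantification and differential acetylation
#'
#' Per-sample H3K27ac peak calls are merged by single-linkage clustering on
#' summit distance (summits closer than 1 kb on the same chromosome join one
#' merged region). Signal is raw read-interval coverage per merged region,
#' normalized by total mapped reads (per million) and region length (per
#' kb), with matched input coverage subtracted and negative values floored
#' at zero. Differential acetylation applies the NB Wald test to the
#' rounded normalized signal with size factors fixed at 1, calling
#' hyper-/hypo-acetylated regions at raw p < 0.05 and |log2FC| >= 1 (FLHS
#' relative to control).
#'
#' @name chip-quant
NULL

#' Merge per-sample peaks by summit distance
#'
#' Single-linkage: two peaks on the same chromosome join the same merged
#' region when their summits are less than `summit_dist` bp apart; linkage
#' chains, so a merged region's span can exceed `summit_dist`. The merged
#' interval is the union of constituent intervals; the consensus summit is
#' the summit of the constituent with the highest score (ties resolved to
#' the leftmost summit).
#'
#' @param peak_sets A list (one element per sample) of peak data.frames as
#'   returned by [read_narrowpeak()], or a single combined data.frame.
#' @param summit_dist Merge threshold in bp (default 1000; strict less-than).
#' @return data.frame of merged peaks: `peak_id`, `chrom`, `start`, `end`,
#'   `summit`, `n_constituents`, and a list-column `constituents` of
#'   constituent peak ids.
#' @export
merge_peaks <- function(peak_sets, summit_dist = 1000) {
  all <- if (is.data.frame(peak_sets)) peak_sets else do.call(rbind, peak_sets)
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(peak_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      summit = integer(0), n_constituents = integer(0)))
  }
  if (!"score" %in% names(all)) all$score <- 0
  ord <- order(all$chrom, all$summit, all$start)
  all <- all[ord, ]
  # cluster: within a chromosome, consecutive summit gaps < summit_dist chain
  new_chrom <- c(TRUE, all$chrom[-1] != all$chrom[-nrow(all)])
  gap <- c(Inf, diff(all$summit))
  breaks <- new_chrom | gap >= summit_dist
  cluster <- cumsum(breaks)
  sp <- split(seq_len(nrow(all)), cluster)
  rows <- lapply(sp, function(ii) {
    x <- all[ii, ]
    best <- which(x$score == max(x$score))
    summit <- min(x$summit[best])
    data.frame(chrom = x$chrom[1], start = min(x$start), end = max(x$end),
               summit = summit, n_constituents = nrow(x),
               stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, rows)
  merged$peak_id <- sprintf("mp%05d", seq_len(nrow(merged)))
  merged$constituents <- I(lapply(sp, function(ii) all$peak_id[ii]))
  rownames(merged) <- NULL
  merged[, c("peak_id", "chrom", "start", "end", "summit",
             "n_constituents", "constituents")]
}

#' Count read intervals overlapping merged peaks
#'
#' A read contributes to a merged peak when their half-open intervals share
#' at least 1 bp; an abutting read (read end equal to peak start) does not
#' count. Reads on chromosomes absent from the peak set are skipped with a
#' message.
#'
#' @param reads_by_sample Named list of read data.frames (`chrom`, `start`,
#'   `end`), one per sample.
#' @param merged_peaks Merged peak data.frame from [merge_peaks()].
#' @return Integer matrix, merged peaks x samples.
#' @export
quantify <- function(reads_by_sample, merged_peaks) {
  pk <- GenomicRanges::GRanges(merged_peaks$chrom,
                               IRanges::IRanges(merged_peaks$start + 1L,
                                                merged_peaks$end))
  out <- matrix(0L, nrow(merged_peaks), length(reads_by_sample),
                dimnames = list(merged_peaks$peak_id, names(reads_by_sample)))
  for (j in seq_along(reads_by_sample)) {
    rd <- reads_by_sample[[j]]
    known <- rd$chrom %in% merged_peaks$chrom
    if (any(!known)) {
      message(sum(!known), " read(s) on unknown chromosome skipped for sample ",
              names(reads_by_sample)[j])
      rd <- rd[known, , drop = FALSE]
    }
    if (nrow(rd) == 0) next
    gr <- GenomicRanges::GRanges(rd$chrom,
                                 IRanges::IRanges(rd$start + 1L, rd$end))
    out[, j] <- GenomicRanges::countOverlaps(pk, gr, minoverlap = 1L)
  }
  out
}

#' Normalize coverage and subtract input
#'
#' Each raw count is scaled to reads-per-million per kilobase of peak:
#' norm = raw / (total/1e6 * length/1e3); the normalized input is then
#' subtracted from the normalized ChIP signal and negative values are
#' floored at zero.
#'
#' @param chip_raw,input_raw Matrices (peaks x samples) of raw counts; input
#'   columns must cover the ChIP samples (matched by column name).
#' @param chip_totals,input_totals Named per-sample total mapped read counts.
#' @param peak_lengths Merged peak lengths in bp.
#' @return List with `norm_chip`, `norm_input`, and floored `signal`
#'   matrices.
#' @export
normalize_subtract <- function(chip_raw, input_raw, chip_totals, input_totals,
                               peak_lengths) {
  samples <- colnames(chip_raw)
  missing_in <- setdiff(samples, colnames(input_raw))
  if (length(missing_in) > 0) {
    stop("missing input sample(s): ", paste(missing_in, collapse = ", "))
  }
  missing_tot <- setdiff(samples, names(chip_totals))
  if (length(missing_tot) > 0) {
    stop("missing ChIP total for sample(s): ", paste(missing_tot, collapse = ", "))
  }
  if (any(chip_totals[samples] <= 0) || any(input_totals[samples] <= 0)) {
    stop("total mapped read counts must be positive")
  }
  norm <- function(raw, totals) {
    sweep(raw / (peak_lengths / 1e3), 2, totals[colnames(raw)] / 1e6, "/")
  }
  nc <- norm(chip_raw, chip_totals)
  ni <- norm(input_raw[, samples, drop = FALSE], input_totals)
  list(norm_chip = nc, norm_input = ni, signal = pmax(nc - ni, 0))
}

#' Differential acetylation between groups
#'
#' Applies the NB Wald test to the normalized input-subtracted signal
#' rounded to the nearest integer, with size factors fixed at 1 (depth
#' normalization has already been applied). Regions with raw p < 0.05 and
#' |log2FC| >= 1 are labelled hyper-acetylated (up in the case group) or
#' hypo-acetylated.
#'
#' @param signal Normalized subtracted signal matrix (peaks x samples).
#' @param group Two-level group vector; first level is the control/reference.
#' @param params [nb_params()]; defaults to the raw-p rule
#'   (`use_adjusted = FALSE`, threshold 0.05, |log2FC| >= 1).
#' @return data.frame as from [nb_wald_test()] with `direction` recoded to
#'   hyper/hypo/ns.
#' @export
differential_acetylation <- function(signal, group,
                                     params = nb_params(use_adjusted = FALSE)) {
  res <- nb_wald_test(round(signal), group, sf = 1, params = params)
  res$direction <- c(up = "hyper", down = "hypo", ns = "ns")[res$direction]
  res
}
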