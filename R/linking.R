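#' Correlation-based peak-gene linking
#'
#' Candidate target genes for differential H3K27ac peaks are all genes whose
#' TSS lies within 1 Mb of the peak summit on the same chromosome. Each
#' candidate pair is scored by the Pearson correlation between the peak's
#' normalized subtracted signal and the gene's FPKM across the matched
#' samples, with a two-sided p-value from the t-transform
#' t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom. Linked pairs
#' satisfy |r| > 0.8 and p < 0.01; note that at n = 6 the p < 0.01 clause is
#' the binding constraint (it implies |r| > ~0.917).
#'
#' @name peak-gene-linking
NULL

#' Enumerate candidate peak-gene pairs within a window
#'
#' @param diff_peaks data.frame of peaks with `peak_id`, `chrom`, `summit`
#'   (typically the differential subset of merged peaks).
#' @param annotation A `genome_annotation`.
#' @param window Maximum summit-to-TSS distance in bp (default 1e6).
#' @return data.frame with `peak_id`, `gene_id`, `chrom`, `distance`.
#' @export
candidate_pairs <- function(diff_peaks, annotation, window = 1e6) {
  g <- annotation$genes
  tss <- annotation$tss
  tss_chrom <- g$chrom[match(names(tss), g$gene_id)]
  out <- vector("list", nrow(diff_peaks))
  for (i in seq_len(nrow(diff_peaks))) {
    same <- tss_chrom == diff_peaks$chrom[i]
    d <- abs(tss[same] - diff_peaks$summit[i])
    keep <- d <= window
    if (!any(keep)) next
    out[[i]] <- data.frame(peak_id = diff_peaks$peak_id[i],
                           gene_id = names(tss[same])[keep],
                           chrom = diff_peaks$chrom[i],
                           distance = as.integer(d[keep]),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      chrom = character(0), distance = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation link test
#'
#' @param x,y Numeric vectors of equal length n >= 3 (peak signal and gene
#'   abundance across the same samples, in the same order).
#' @return List with `r`, `p`, and `reason` (`NA` unless the test is
#'   undefined, e.g. a constant vector).
#' @export
link_test <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch between peak and gene vectors")
  n <- length(x)
  if (n < 3) stop("need at least 3 samples for the correlation test")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, reason = "constant vector"))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, reason = NA_character_)
}

#' Score candidate pairs
#'
#' Runs [link_test()] for every candidate pair; pairs whose test is
#' undefined (constant vectors) are dropped with a message.
#'
#' @param pairs data.frame from [candidate_pairs()].
#' @param peak_signal Matrix of normalized subtracted signal, peak ids as
#'   rownames, samples as columns.
#' @param gene_abundance Matrix of FPKM, gene ids as rownames, the same
#'   sample columns in the same order.
#' @return `pairs` with `r`, `p` and `sign` columns added.
#' @export
score_links <- function(pairs, peak_signal, gene_abundance) {
  if (!identical(colnames(peak_signal), colnames(gene_abundance))) {
    stop("peak signal and gene abundance must share the same sample columns")
  }
  r <- p <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    lt <- link_test(peak_signal[pairs$peak_id[i], ],
                    gene_abundance[pairs$gene_id[i], ])
    r[i] <- lt$r; p[i] <- lt$p
  }
  undef <- is.na(r)
  if (any(undef)) message(sum(undef), " pair(s) dropped: undefined correlation")
  pairs <- pairs[!undef, , drop = FALSE]
  pairs$r <- r[!undef]
  pairs$p <- p[!undef]
  pairs$sign <- ifelse(pairs$r >= 0, "positive", "negative")
  rownames(pairs) <- NULL
  pairs
}

#' Select significant peak-gene links
#'
#' Keeps pairs with |r| > `r_min` and p < `p_max`, in deterministic order
#' (peak id, then gene id).
#'
#' @param scored data.frame from [score_links()].
#' @param r_min Correlation threshold (default 0.8, strict).
#' @param p_max p-value threshold (default 0.01, strict).
#' @return Filtered, ordered data.frame of links.
#' @export
select_links <- function(scored, r_min = 0.8, p_max = 0.01) {
  keep <- abs(scored$r) > r_min & scored$p < p_max
  out <- scored[keep, , drop = FALSE]
  out <- out[order(out$peak_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top peak-associated genes per acetylation direction
#'
#' Joins links to peak direction labels, then per direction sorts by p
#' ascending, |r| descending, gene id, deduplicates genes keeping each
#' gene's best link, and truncates to `k`.
#'
#' @param links Selected links (with `peak_id`, `gene_id`, `r`, `p`).
#' @param diff_results Differential acetylation results with `feature` and
#'   `direction` (hyper/hypo/ns).
#' @param k List length per direction (default 100).
#' @return List with `hyper` and `hypo` data.frames of ranked genes.
#' @export
top_peak_genes <- function(links, diff_results, k = 100) {
  links$peak_direction <- diff_results$direction[match(links$peak_id,
                                                       diff_results$feature)]
  pick <- function(dir) {
    x <- links[!is.na(links$peak_direction) & links$peak_direction == dir, ,
               drop = FALSE]
    if (nrow(x) == 0) return(x)
    x <- x[order(x$p, -abs(x$r), x$gene_id), , drop = FALSE]
    x <- x[!duplicated(x$gene_id), , drop = FALSE]
    if (nrow(x) < k) message(dir, ": only ", nrow(x), " genes available (k = ", k, ")")
    out <- utils::head(x, k)
    rownames(out) <- NULL
    out
  }
  list(hyper = pick("hyper"), hypo = pick("hypo"))
}

#' Distance-decay histogram of links
#'
#' Counts links in `bin_width` bins of summit-TSS distance over
#' `[0, max_dist]`, split by correlation sign and peak direction. Bin
#' counts sum to the number of links within range.
#'
#' @param links Links with `distance`, `sign`, and (optionally)
#'   `peak_direction` columns.
#' @param bin_width Bin width in bp (default 1e5).
#' @param max_dist Histogram range in bp (default 1e6).
#' @return data.frame with `bin_start`, `bin_end`, `sign`,
#'   `peak_direction`, `count`.
#' @export
distance_decay <- function(links, bin_width = 1e5, max_dist = 1e6) {
  edges <- seq(0, max_dist, by = bin_width)
  if (!"peak_direction" %in% names(links)) links$peak_direction <- "all"
  signs <- c("positive", "negative")
  dirs <- unique(links$peak_direction)
  if (length(dirs) == 0) dirs <- "all"
  grid <- expand.grid(bin = seq_len(length(edges) - 1), sign = signs,
                      peak_direction = dirs, stringsAsFactors = FALSE)
  grid$bin_start <- edges[grid$bin]
  grid$bin_end <- edges[grid$bin + 1]
  grid$count <- 0L
  if (nrow(links) > 0) {
    b <- findInterval(links$distance, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
    inr <- b >= 1 & b <= length(edges) - 1
    tab <- table(bin = b[inr], sign = links$sign[inr],
                 peak_direction = links$peak_direction[inr])
    for (i in seq_len(nrow(grid))) {
      bi <- as.character(grid$bin[i])
      if (bi %in% dimnames(tab)$bin &&
          grid$sign[i] %in% dimnames(tab)$sign &&
          grid$peak_direction[i] %in% dimnames(tab)$peak_direction) {
        grid$count[i] <- tab[bi, grid$sign[i], grid$peak_direction[i]]
      }
    }
  }
  grid[, c("bin_start", "bin_end", "sign", "peak_direction", "count")]
}
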