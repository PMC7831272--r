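#' Differential expression: filtering, normalization and NB Wald testing
#'
#' A self-contained negative-binomial Wald test for two-group replicated
#' count data. The model is NB with variance mu + alpha * mu^2; per-feature
#' dispersion is estimated by pooled within-group method of moments, floored,
#' and moderated toward the across-feature median. The Wald statistic is the
#' log2 fold change divided by a delta-method standard error, referred to a
#' two-sided normal distribution, with Benjamini-Hochberg correction across
#' features. Deviations from full GLM machinery (no dispersion trend, no
#' Cox-Reid adjustment, no fold-change shrinkage, no independent filtering)
#' are deliberate and documented.
#'
#' @name rnaseq-diff
NULL

#' NB Wald test parameters
#'
#' @param pseudocount Added to group means inside the log2 ratio (default 0.5).
#' @param dispersion_floor Lower bound on the method-of-moments dispersion.
#' @param moderation Weight in `[0,1]` pulling each feature's dispersion
#'   toward the across-feature median (default 0.5); at replicate counts of
#'   3 per group the raw per-feature estimate is too unstable to use alone.
#' @param padj_threshold Significance threshold on the adjusted (or raw)
#'   p-value used for the direction label.
#' @param lfc_threshold Absolute log2 fold-change threshold for the
#'   direction label (default 1).
#' @param use_adjusted Label directions from the BH-adjusted p-value
#'   (`TRUE`, the expression rule) or the raw p-value (`FALSE`, the
#'   acetylation rule).
#' @return A list of class `nb_params`.
#' @export
nb_params <- function(pseudocount = 0.5, dispersion_floor = 1e-8,
                      moderation = 0.5, padj_threshold = 0.05,
                      lfc_threshold = 1, use_adjusted = TRUE) {
  stopifnot(pseudocount > 0, dispersion_floor >= 0,
            moderation >= 0, moderation <= 1)
  structure(list(pseudocount = pseudocount, dispersion_floor = dispersion_floor,
                 moderation = moderation, padj_threshold = padj_threshold,
                 lfc_threshold = lfc_threshold, use_adjusted = use_adjusted),
            class = "nb_params")
}

#' Remove lowly expressed features
#'
#' A feature is removed when the proportion of samples with a count below
#' `min_count` is at least `sample_frac` (the "counts across 90% of samples
#' are lower than 2" rule, read with >= on the sample proportion). Feature
#' order is preserved.
#'
#' @param counts Numeric matrix, features x samples.
#' @param min_count Count threshold (default 2).
#' @param sample_frac Proportion-of-samples threshold (default 0.9).
#' @return The filtered matrix.
#' @export
filter_low_expression <- function(counts, min_count = 2, sample_frac = 0.9) {
  if (nrow(counts) == 0 || ncol(counts) == 0) return(counts)
  low <- rowMeans(counts < min_count)
  counts[low < sample_frac, , drop = FALSE]
}

#' FPKM normalization
#'
#' FPKM_ij = count_ij / (length_i/1e3 * libsize_j/1e6).
#'
#' @param counts Numeric matrix, features x samples.
#' @param lengths Feature lengths in bp, aligned with rows.
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return Matrix of FPKM values.
#' @export
fpkm <- function(counts, lengths, lib_sizes = colSums(counts)) {
  if (length(lengths) != nrow(counts)) stop("lengths must match rows of counts")
  if (any(lengths <= 0)) stop("zero or negative feature length")
  if (any(lib_sizes <= 0)) stop("zero library size")
  sweep(counts / (lengths / 1e3), 2, lib_sizes / 1e6, "/")
}

#' Median-of-ratios size factors
#'
#' For features positive in every sample, each sample's factor is the median
#' ratio of its counts to the per-feature geometric mean. When no feature is
#' positive in all samples, falls back to library size over mean library
#' size with a warning.
#'
#' @param counts Numeric matrix, features x samples.
#' @return Positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos)) {
    warning("no feature positive in all samples; falling back to library-size factors")
    ls <- colSums(counts)
    return(ls / mean(ls))
  }
  m <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  apply(m / geo, 2, stats::median)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1; input
#' order is preserved.
#'
#' @param p Vector of p-values in `[0,1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test for two groups
#'
#' Counts are divided by per-sample size factors; group means m_A, m_B give
#' log2FC = log2((m_B + pc) / (m_A + pc)). Per-feature dispersion alpha is
#' the pooled within-group method-of-moments estimate (v - mu)/mu^2, floored
#' and moderated toward the across-feature median. The delta-method variance
#' of each group mean, (m_g + alpha * m_g^2) / n_g, yields the standard
#' error of log2FC; z = log2FC / SE is referred to a two-sided normal
#' distribution and BH-adjusted. Features with zero mean in both groups get
#' p = 1 and log2FC = 0.
#'
#' @param counts Numeric matrix, features x samples.
#' @param group Factor or vector of two group labels; the first level is the
#'   reference (log2FC is second level over first).
#' @param sf Per-sample size factors; `NULL` computes median-of-ratios
#'   factors, a single 1 fixes all at 1.
#' @param params An [nb_params()] list.
#' @return data.frame with `feature`, `baseMean`, `log2FC`, `p`, `padj`,
#'   `direction` (up/down/ns).
#' @export
nb_wald_test <- function(counts, group, sf = NULL, params = nb_params()) {
  if (!is.factor(group)) group <- factor(group, levels = unique(group))
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (any(table(group) < 2)) stop("need >= 2 samples per group")
  if (is.null(sf)) sf <- size_factors(counts)
  if (length(sf) == 1) sf <- rep(sf, ncol(counts))
  norm <- sweep(counts, 2, sf, "/")
  a_idx <- group == levels(group)[1]
  b_idx <- !a_idx
  nA <- sum(a_idx); nB <- sum(b_idx)
  mA <- rowMeans(norm[, a_idx, drop = FALSE])
  mB <- rowMeans(norm[, b_idx, drop = FALSE])
  vA <- apply(norm[, a_idx, drop = FALSE], 1, stats::var)
  vB <- apply(norm[, b_idx, drop = FALSE], 1, stats::var)
  v <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  mu <- (nA * mA + nB * mB) / (nA + nB)
  alpha <- (v - mu) / mu^2
  alpha[!is.finite(alpha)] <- params$dispersion_floor
  alpha <- pmax(params$dispersion_floor, alpha)
  alpha <- (1 - params$moderation) * alpha +
    params$moderation * stats::median(alpha)
  pc <- params$pseudocount
  lfc <- log2((mB + pc) / (mA + pc))
  varA <- (mA + alpha * mA^2) / nA
  varB <- (mB + alpha * mB^2) / nB
  se <- sqrt(varA / (mA + pc)^2 + varB / (mB + pc)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  both_zero <- mA == 0 & mB == 0
  p[both_zero] <- 1
  lfc[both_zero] <- 0
  padj <- bh_adjust(p)
  crit <- if (params$use_adjusted) padj else p
  sig <- if (params$use_adjusted) crit <= params$padj_threshold else crit < params$padj_threshold
  direction <- ifelse(sig & lfc >= params$lfc_threshold, "up",
                      ifelse(sig & lfc <= -params$lfc_threshold, "down", "ns"))
  data.frame(feature = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts))) else rownames(counts),
             baseMean = (mA + mB) / 2, log2FC = lfc, p = p, padj = padj,
             direction = direction, stringsAsFactors = FALSE)
}
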