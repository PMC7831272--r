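#' qPCR quantification arithmetic
#'
#' Cycle-threshold (Ct) arithmetic for ChIP-qPCR and RT-qPCR validation:
#' percent of input, fold enrichment of a positive over a negative locus,
#' and relative expression by the 2^-ddCt method against a housekeeping
#' reference. One qPCR cycle corresponds to a factor of 2 in template
#' abundance throughout (no amplification-efficiency correction).
#'
#' @name qpcr
NULL

#' Percent of input for a ChIP sample
#'
#' The input Ct is first adjusted for the input dilution: a fraction f of
#' chromatin saved as input corresponds to log2(1/f) extra cycles, so
#' adjusted input Ct = ct_input - log2(1/f). Then
#' percent = 100 * 2^-(ct_chip - adjusted input Ct).
#'
#' @param ct_chip,ct_input Ct values (cycles), positive.
#' @param input_fraction Fraction of chromatin used as input, in (0, 1].
#' @return Percent of input on a 0-100 scale.
#' @export
percent_input <- function(ct_chip, ct_input, input_fraction) {
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("input_fraction must lie in (0, 1]")
  }
  if (any(ct_chip <= 0) || any(ct_input <= 0)) stop("Ct values must be positive")
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(-(ct_chip - adjusted))
}

#' Fold enrichment of a positive locus over a negative locus
#'
#' ddCt = dct_negative - dct_positive, oriented so that stronger
#' enrichment at the positive locus gives fold > 1; fold = 2^ddCt.
#'
#' @param dct_positive,dct_negative Per-locus delta-Ct values (ChIP minus
#'   adjusted input).
#' @return Fold enrichment.
#' @export
fold_enrichment <- function(dct_positive, dct_negative) {
  2^(dct_negative - dct_positive)
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal);
#' fold = 2^-ddCt, i.e. expression of the target normalized to the
#' reference gene, relative to the calibrator condition.
#'
#' @param ct_target,ct_reference Sample Ct for the target and reference
#'   (housekeeping) gene.
#' @param ct_target_cal,ct_reference_cal Calibrator-condition Ct values.
#' @return Fold change in relative expression.
#' @export
relative_expression <- function(ct_target, ct_reference,
                                ct_target_cal, ct_reference_cal) {
  ddct <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  2^(-ddct)
}

#' Summarize a replicated Ct table
#'
#' @param ct_table data.frame with columns `locus`, `condition`,
#'   `replicate`, `ct`.
#' @return data.frame of per-locus, per-condition mean Ct, SD and n.
#' @export
summarize_ct <- function(ct_table) {
  need <- c("locus", "condition", "replicate", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  agg <- stats::aggregate(ct ~ locus + condition, data = ct_table,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(locus = agg$locus, condition = agg$condition,
                    mean_ct = agg$ct[, "mean"], sd_ct = agg$ct[, "sd"],
                    n = agg$ct[, "n"], stringsAsFactors = FALSE)
  out[order(out$locus, out$condition), ]
}
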