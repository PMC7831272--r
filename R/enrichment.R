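#' Motif and gene-set enrichment
#'
#' A log-odds PWM scanner with a relative score threshold stands in for
#' known-motif scanning, and one-sided hypergeometric upper-tail tests give
#' both motif enrichment (sequences with at least one hit, target set drawn
#' from the pooled target+background collection) and gene-set
#' over-representation (query against a gene universe and GMT sets), with
#' BH correction across sets.
#'
#' @name enrichment
NULL

#' Construct a position weight matrix object
#'
#' @param mat L x 4 matrix of base probabilities, columns A, C, G, T; rows
#'   must sum to 1 (tolerance 1e-6) and L >= 4. Probabilities are clamped
#'   to at least 1e-4 (then renormalized) so log-odds scores stay finite.
#' @param name Motif name.
#' @param background Background base probabilities (default uniform).
#' @return Object of class `pwm`.
#' @export
pwm <- function(mat, name = "motif", background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(mat) < 4) stop("PWM must have length >= 4")
  if (any(abs(rowSums(mat) - 1) > 1e-6)) stop("PWM rows must sum to 1")
  mat <- pmax(mat, 1e-4)
  mat <- mat / rowSums(mat)
  colnames(mat) <- c("A", "C", "G", "T")
  structure(list(name = name, mat = mat, background = background),
            class = "pwm")
}

#' Read PWMs from JASPAR-style text
#'
#' Format per motif: a `>name` header then four lines `A [ n n ... ]` etc.
#' Counts (or probabilities) are column-normalized to probabilities.
#'
#' @param path PWM text file (may contain several motifs).
#' @return Named list of `pwm` objects.
#' @export
read_pwms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no PWM header ('>name') found in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    nm <- sub("^>\\s*", "", lines[i])
    nm <- strsplit(nm, "\\s+")[[1]][1]
    block <- lines[(i + 1):(i + 4)]
    rows <- lapply(block, function(ln) {
      base <- sub("^([ACGT]).*", "\\1", ln)
      body <- gsub("[^0-9.eE+-]", " ", sub("^[ACGT]", "", ln))
      nums <- strsplit(trimws(body), "\\s+")[[1]]
      list(base = base, val = as.numeric(nums))
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, c("A", "C", "G", "T"))) {
      stop("PWM block for ", nm, " must have A, C, G, T rows")
    }
    vals <- do.call(rbind, lapply(rows[order(match(bases, c("A", "C", "G", "T")))],
                                  `[[`, "val"))  # 4 x L counts, rows A,C,G,T
    if (length(unique(lengths(lapply(rows, `[[`, "val")))) != 1) {
      stop("ragged PWM block for ", nm)
    }
    probs <- t(vals)
    probs <- probs / rowSums(probs)
    out[[nm]] <- pwm(probs, name = nm)
  }
  out
}

#' Scan a sequence with a PWM
#'
#' Scores every window of length L on both strands with the log2-odds score
#' sum(log2(p_base / background)); a window is a hit when its score reaches
#' `rel_threshold` times the maximum achievable score. Windows containing N
#' are skipped. A zero-information PWM (maximum score <= 0) is unscannable:
#' an empty hit table is returned with a warning and attribute
#' `unscannable = TRUE`.
#'
#' @param sequence Character scalar over A, C, G, T, N.
#' @param pwm A [pwm()] object.
#' @param rel_threshold Fraction of the maximum score required for a hit
#'   (default 0.8).
#' @return data.frame with 0-based `position`, `strand`, `score`.
#' @export
scan_pwm <- function(sequence, pwm, rel_threshold = 0.8) {
  S <- log2(pwm$mat / rep(pwm$background, each = nrow(pwm$mat)))
  L <- nrow(S)
  max_score <- sum(apply(S, 1, max))
  empty <- data.frame(position = integer(0), strand = character(0),
                      score = numeric(0))
  if (max_score <= 0) {
    warning("zero-information PWM '", pwm$name, "': unscannable")
    attr(empty, "unscannable") <- TRUE
    return(empty)
  }
  n <- nchar(sequence)
  if (n < L) return(empty)
  code <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  nw <- n - L + 1
  fwd <- rev <- rep(0, nw)
  ok <- rep(TRUE, nw)
  for (k in seq_len(L)) {
    b <- code[k:(k + nw - 1)]
    bad <- is.na(b)
    ok <- ok & !bad
    b[bad] <- 1L
    fwd <- fwd + S[k, b]
    rev <- rev + S[L - k + 1, 5L - b]  # reverse strand: complement, reversed
  }
  thr <- rel_threshold * max_score
  hit_f <- ok & fwd >= thr
  hit_r <- ok & rev >= thr
  data.frame(
    position = c(which(hit_f), which(hit_r)) - 1L,
    strand = c(rep("+", sum(hit_f)), rep("-", sum(hit_r))),
    score = c(fwd[hit_f], rev[hit_r]),
    stringsAsFactors = FALSE
  )
}

#' Which sequences contain at least one motif hit
#'
#' @param seqs Named character vector of sequences.
#' @param pwm A [pwm()] object.
#' @param rel_threshold Passed to [scan_pwm()].
#' @return Named logical vector.
#' @export
has_motif <- function(seqs, pwm, rel_threshold = 0.8) {
  vapply(seqs, function(s) nrow(scan_pwm(s, pwm, rel_threshold)) > 0, TRUE)
}

hypergeom_upper <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Motif enrichment in target versus background sequences
#'
#' Counts sequences with at least one hit in the target and background sets
#' and tests the target count with a one-sided hypergeometric upper tail,
#' drawing `length(target_seqs)` sequences from the pooled collection.
#'
#' @param target_seqs,background_seqs Named character vectors of sequences.
#' @param pwm A [pwm()] object.
#' @param rel_threshold Passed to [scan_pwm()].
#' @return One-row data.frame: `name`, `overlap` (targets with motif),
#'   `target_size`, `universe`, `set_size` (pooled sequences with motif),
#'   `p`, `frac_targets`.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwm,
                             rel_threshold = 0.8) {
  if (length(target_seqs) == 0) stop("empty target sequence set")
  if (length(background_seqs) == 0) stop("empty background sequence set")
  th <- has_motif(target_seqs, pwm, rel_threshold)
  bh <- has_motif(background_seqs, pwm, rel_threshold)
  k <- sum(th)
  K <- k + sum(bh)
  N <- length(th) + length(bh)
  n <- length(th)
  data.frame(name = pwm$name, overlap = k, target_size = n, universe = N,
             set_size = K, p = hypergeom_upper(k, K, N, n),
             frac_targets = k / n, stringsAsFactors = FALSE)
}

#' Rank a PWM collection by enrichment
#'
#' @param target_seqs,background_seqs Sequence sets.
#' @param pwms List of [pwm()] objects.
#' @param rel_threshold Passed to [scan_pwm()].
#' @return data.frame, one row per motif, BH-adjusted and sorted by p.
#' @export
motif_enrichment_table <- function(target_seqs, background_seqs, pwms,
                                   rel_threshold = 0.8) {
  res <- do.call(rbind, lapply(pwms, function(m) {
    motif_enrichment(target_seqs, background_seqs, m, rel_threshold)
  }))
  res$padj <- bh_adjust(res$p)
  res <- res[order(res$p, res$name), ]
  rownames(res) <- NULL
  res
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, tests the overlap between the query and the set within the
#' universe with a hypergeometric upper tail; p-values are BH-corrected
#' across sets. Query genes absent from the universe are dropped with a
#' message.
#'
#' @param query_genes Character vector of gene ids.
#' @param universe_genes Character vector (the tested background).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @return data.frame with `name`, `overlap`, `target_size`, `universe`,
#'   `set_size`, `p`, `padj`, `frac_targets`, sorted by p.
#' @export
geneset_enrichment <- function(query_genes, universe_genes, gene_sets) {
  universe_genes <- unique(universe_genes)
  if (length(universe_genes) == 0) stop("empty gene universe")
  query_genes <- unique(query_genes)
  out <- setdiff(query_genes, universe_genes)
  if (length(out) > 0) {
    message(length(out), " query gene(s) not in universe dropped")
    query_genes <- intersect(query_genes, universe_genes)
  }
  N <- length(universe_genes)
  n <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe_genes)
    K <- length(set)
    k <- length(intersect(query_genes, set))
    data.frame(name = nm, overlap = k, target_size = n, universe = N,
               set_size = K, p = hypergeom_upper(k, K, N, n),
               frac_targets = if (n > 0) k / n else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$p)
  res <- res[order(res$p, res$name), ]
  rownames(res) <- NULL
  res
}
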