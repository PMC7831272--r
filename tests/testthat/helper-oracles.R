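# Independent brute-force oracles used to validate the package's
# implementations. These are deliberately naive O(n^2) / enumeration
# routines kept separate from the code paths they check.

# literal step-up BH: q_(k) = n p_(k) / k, adjusted_(k) = min_{j >= k} q_(j)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- n * p[o] / seq_len(n)
  adj <- numeric(n)
  for (k in seq_len(n)) adj[k] <- min(1, min(q[k:n]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# single-linkage merge oracle: connected components of the graph with an
# edge between peaks on the same chromosome with |summit_i - summit_j| < d
single_linkage_oracle <- function(peaks, d) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && peaks$chrom[i] == peaks$chrom[j] &&
          abs(peaks$summit[i] - peaks$summit[j]) < d) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  split(seq_len(n), roots)
}

# direct-summation Pearson correlation
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# exhaustive hypergeometric upper tail P(X >= k) via binomial coefficients
hyper_tail_oracle <- function(k, K, N, n) {
  j <- max(0, k):min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# reverse complement for strand-symmetry checks
revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
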