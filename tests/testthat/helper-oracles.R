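# Independent oracles shared across test files.

# Exhaustive enumeration oracle for the analytic score distribution: pmf
# over the same discretized raw-score grid, assembled per k-mer instead of
# by convolution.
enumGridPmf <- function(m, baseFreqs, bin = 1e-4) {
  L <- log2(motifMatrix(m) / 0.25)
  idx <- round(L / bin)
  k <- ncol(L)
  kmers <- allKmers(k)
  bases <- c(A = 1L, C = 2L, G = 3L, U = 4L)
  chars <- strsplit(kmers, "")
  sums <- vapply(chars, function(ch)
    sum(idx[cbind(bases[ch], seq_len(k))]), numeric(1L))
  probs <- vapply(chars, function(ch) prod(baseFreqs[bases[ch]]),
                  numeric(1L))
  agg <- tapply(probs, sums, sum)
  list(idxSum = as.numeric(names(agg)), prob = as.numeric(agg))
}

# Brute-force hypergeometric upper-tail (one-tailed Fisher) oracle.
fisherOracle <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  K <- a + c
  xs <- a:min(m1, K)
  sum(choose(m1, xs) * choose(m2, K - xs)) / choose(m1 + m2, K)
}
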