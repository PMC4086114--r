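# Shared test motifs, backgrounds and small generators. Heavy objects are
# memoized so multiple test files reuse one build.

.testCache <- new.env(parent = emptyenv())

# FOX-family UGCAUG-like PSSM: dominant base 0.8, others equal. Non-periodic,
# so overlapping windows of a hit are essentially background.
foxMotif <- function() {
  cons <- c(4L, 3L, 2L, 1L, 4L, 3L)  # U G C A U G over (A,C,G,U)
  mat <- matrix(0.2 / 3, 4L, 6L)
  for (j in seq_along(cons)) mat[cons[j], j] <- 0.8
  Motif("fox1_pssm", mat, protein = "FOX1")
}

# Random well-conditioned PSSM (entries bounded away from ties).
randomPssm <- function(k, seed, id = sprintf("rnd_k%d_s%d", k, seed)) {
  set.seed(seed)
  mat <- vapply(seq_len(k), function(j) {
    p <- runif(4, 0.05, 1)
    p / sum(p)
  }, numeric(4L))
  Motif(id, mat, origin = "pssm")
}

# Background model for the FOX motif over the intergenic fixture class,
# built once per test run (study conditions: 1000 x 250 nt).
foxBackground <- function() {
  if (!exists("foxBg", envir = .testCache)) {
    fx <- generateFixtures(foxMotif(), seed = 11L, nBackground = 1000L,
                           backgroundLength = 250L,
                           backgroundClasses = "mid_intron_intergenic",
                           nStrong = 0L, nWeak = 0L)
    assign("foxBgSeqs", fx$background$mid_intron_intergenic,
           envir = .testCache)
    assign("foxBg",
           buildBackground(foxMotif(), fx$background$mid_intron_intergenic),
           envir = .testCache)
  }
  get("foxBg", envir = .testCache)
}

foxBackgroundSeqs <- function() {
  foxBackground()
  get("foxBgSeqs", envir = .testCache)
}

# iid sequences from a base composition (A,C,G,U)
randSeqs <- function(n, len, freqs = rep(0.25, 4)) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = freqs),
          collapse = ""), character(1L))
}

# All 4^k k-mers (k <= 8), as character vector
allKmers <- function(k) {
  g <- do.call(expand.grid, rep(list(c("A", "C", "G", "U")), k))
  apply(as.matrix(g[, k:1, drop = FALSE]), 1L, paste, collapse = "")
}
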