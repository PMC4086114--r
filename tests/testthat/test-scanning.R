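test_that("match score hits its exact anchors and hand-computed values", {
  m <- foxMotif()
  expect_equal(matchScore(m, "UGCAUG"), 1)
  # column-wise argmin k-mer scores exactly 0 (any non-0.8 base works per
  # column; all non-dominant entries are equal)
  expect_equal(matchScore(m, "AAGGAA"), 0)
  expect_true(is.na(matchScore(m, "UGCNUG")))
  expect_error(matchScore(m, "UGCA"), "length")

  # independent arithmetic oracle on a 3-column motif
  mat <- cbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.6, 0.2, 0.1),
               c(0.25, 0.25, 0.25, 0.25))
  m3 <- Motif("hand", mat)
  p <- motifMatrix(m3)  # flooring is a no-op here (no zero entries)
  raw <- log2(p["A", 1] / 0.25) + log2(p["G", 2] / 0.25) +
    log2(p["U", 3] / 0.25)
  smax <- log2(p["A", 1] / 0.25) + log2(p["C", 2] / 0.25) +
    log2(p["A", 3] / 0.25)
  smin <- log2(p["C", 1] / 0.25) + log2(p["A", 2] / 0.25) +
    log2(p["A", 3] / 0.25)
  expect_equal(matchScore(m3, "AGU"), unname((raw - smin) / (smax - smin)),
               tolerance = 1e-12)

  # fully uniform motif: degenerate S_max = S_min branch returns 1
  mN <- parseIUPACConsensus("NNNN", "alln")
  expect_equal(matchScore(mN, "ACGU"), 1)
  expect_equal(matchScore(mN, "UUUU"), 1)
})

test_that("scanning enumerates overlapping windows and skips ambiguity", {
  m <- parseIUPACConsensus("ACGUA", "m5")
  seq21 <- paste0(strrep("ACGUA", 4), "A")
  pos <- scanSequence(m, seq21, seqId = "s")
  expect_equal(nrow(pos), 17L)                    # L - k + 1
  expect_identical(pos$offset, 0:16)
  expect_true(all(diff(pos$offset) > 0))

  withN <- paste0("N", substr(seq21, 2, 21))
  posN <- scanSequence(m, withN)
  expect_identical(posN$offset, 1:16)             # window 0 excluded

  expect_warning(out <- scanSequence(m, "ACG"), "shorter")
  expect_equal(nrow(out), 0L)

  # planted consensus in hand-picked low-scoring flanks: unique score-1 hit
  planted <- paste0(strrep("CA", 10), "ACGUA", strrep("UC", 10))
  sc <- scanSequence(m, planted)
  expect_equal(sc$offset[sc$matchScore == 1], 20L)
  expect_identical(sc$kmer[sc$offset == 20L], "ACGUA")

  # match score is a function of the k-mer only (flank invariance)
  expect_equal(sc$matchScore[sc$offset == 20L], matchScore(m, "ACGUA"))
})

test_that("empirical p-values equal the counting oracle with +1 correction", {
  set.seed(3)
  bg <- runif(1000)
  probe <- c(-1, 0, runif(50), bg[1:20], 1, 2)
  oracle <- vapply(probe, function(s) (1 + sum(bg >= s)) / (1 + 1000),
                   numeric(1L))
  expect_equal(empiricalPvalue(bg, probe), oracle, tolerance = 1e-12)
  expect_equal(empiricalPvalue(bg, min(bg) - 1), 1)
  expect_equal(empiricalPvalue(bg, max(bg) + 1), 1 / 1001)
  # monotone non-increasing in score
  s <- sort(runif(100))
  expect_true(all(diff(empiricalPvalue(bg, s)) <= 0))
})

test_that("threshold_for matches a quantile oracle and is monotone in p", {
  bg <- (0:999) / 1000
  # oracle: smallest sample value whose empirical p-value is < p
  oracleT <- function(p) {
    pv <- vapply(bg, function(t) (1 + sum(bg >= t)) / 1001, numeric(1L))
    bg[which(pv < p)[1]]
  }
  expect_equal(thresholdFor(bg, 0.01), oracleT(0.01))
  expect_equal(thresholdFor(bg, 0.005), oracleT(0.005))
  # top 1%: nine sample points are called at the 0.01 threshold
  expect_equal(sum(bg >= thresholdFor(bg, 0.01)), 9L)
  expect_equal(thresholdFor(bg, 0.999), oracleT(0.999))  # near the minimum
  expect_gte(thresholdFor(bg, 0.005), thresholdFor(bg, 0.01))
  expect_warning(t0 <- thresholdFor(bg, 1e-6), "no score")
  expect_identical(t0, Inf)
})

test_that("analytic score distribution equals exhaustive enumeration", {
  cases <- list(
    list(m = parseIUPACConsensus("ACG", "det3"), f = rep(0.25, 4)),
    list(m = foxMotif(), f = rep(0.25, 4)),
    list(m = randomPssm(5L, 42L), f = c(0.3, 0.2, 0.2, 0.3)),
    list(m = randomPssm(8L, 43L), f = rep(0.25, 4)))
  for (cs in cases) {
    d <- analyticScoreDistribution(cs$m, cs$f)
    oracle <- enumGridPmf(cs$m, cs$f)
    expect_equal(length(d@score), length(oracle$idxSum))
    expect_equal(d@prob, oracle$prob, tolerance = 1e-9)
    # tails agree at every support point
    aTail <- rev(cumsum(rev(d@prob)))
    oTail <- rev(cumsum(rev(oracle$prob)))
    expect_equal(aTail, oTail, tolerance = 1e-9)
    # and the normalized support agrees with direct k-mer scoring
    expect_equal(sum(d@prob), 1, tolerance = 1e-12)
    expect_true(all(d@score >= 0 & d@score <= 1 + 1e-9))
  }
  # deterministic k=3 motif under uniform frequencies: P(score = 1) = 1/64
  d3 <- analyticScoreDistribution(parseIUPACConsensus("ACG", "det3"))
  expect_equal(tailProbability(d3, 1), 1 / 64, tolerance = 1e-12)
  # all-uniform motif: point mass at 1
  dN <- analyticScoreDistribution(parseIUPACConsensus("NNN", "n3"))
  expect_equal(dN@score, 1)
  expect_equal(dN@prob, 1)
})

test_that("theoretical thresholds follow the analytic distribution", {
  # p = 1/64 boundary isolates exactly the best k-mer of a deterministic
  # k=3 motif
  m3 <- parseIUPACConsensus("ACG", "det3")
  th <- theoreticalThreshold(m3, stringencyLevel("medium"))
  thBoundary <- theoreticalThreshold(
    m3, new("StringencyLevel", name = "medium",
            pSignificant = 1 / 64, pSuboptimal = 1 / 64))
  expect_equal(unname(thBoundary["significant"]), 1)
  d <- analyticScoreDistribution(m3)
  expect_equal(tailProbability(d, thBoundary[["significant"]]), 1 / 64,
               tolerance = 1e-12)
  # all-uniform motif: no score is ever significant
  thN <- theoreticalThreshold(parseIUPACConsensus("NNNN", "n4"))
  expect_identical(unname(thN), c(Inf, Inf))
  # ordering holds across motifs and stringencies
  for (m in list(m3, foxMotif(), randomPssm(5L, 9L)))
    for (tier in c("high", "medium", "low")) {
      th <- theoreticalThreshold(m, tier)
      expect_gte(th[["significant"]], th[["suboptimal"]])
    }
})

test_that("background building accounts windows and is split-half stable", {
  m <- foxMotif()
  bg <- foxBackground()
  seqs <- foxBackgroundSeqs()
  expect_equal(nMatch(bg), 1000L * (250L - 6L + 1L))
  expect_false(is.unsorted(matchScores(bg)))
  expect_gt(wrSd(bg), 0)
  expect_gte(bg@nWr, 200L)

  halves <- list(seqs[1:500], seqs[501:1000])
  bgs <- lapply(halves, function(s) buildBackground(m, s))
  se <- sqrt(wrSd(bgs[[1]])^2 / bgs[[1]]@nWr +
             wrSd(bgs[[2]])^2 / bgs[[2]]@nWr)
  expect_lt(abs(wrMean(bgs[[1]]) - wrMean(bgs[[2]])), 3 * se)

  # degenerate all-uniform motif cannot produce a background
  expect_error(
    suppressWarnings(
      buildBackground(parseIUPACConsensus("NNNNNN", "n6"), seqs[1:100])),
    "insufficient|degenerate")
  expect_error(buildBackground(m, seqs[1:3]), "insufficient background")
})

test_that("empirical background converges to the analytic distribution", {
  m <- foxMotif()
  set.seed(17)
  seqs <- randSeqs(41L, 250L)  # uniform composition, ~10,000 windows
  scores <- sort(unlist(lapply(seqs, function(s)
    scanSequence(m, s)$matchScore)))
  expect_gte(length(scores), 10000L)
  d <- analyticScoreDistribution(m)
  cdf <- cumsum(d@prob)
  # KS distance between empirical and analytic CDFs at the support points
  ecdfAt <- vapply(d@score, function(t) mean(scores <= t + 1e-9),
                   numeric(1L))
  expect_lt(max(abs(ecdfAt - cdf)), 0.05)
})
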