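# Constructed scored-position tables for WR arithmetic tests (k = 5).
posTable <- function(offsets, scores) {
  data.frame(seqId = "s", offset = as.integer(offsets),
             kmer = strrep("A", 5L), matchScore = scores,
             stringsAsFactors = FALSE)
}

test_that("anchor filtering equals a brute-force subset", {
  pos <- posTable(c(0, 3, 7, 12, 20), c(0.2, 0.9, 0.5, 0.95, 0.1))
  expect_equal(nrow(findAnchors(pos, 2)), 0L)
  expect_equal(findAnchors(pos, 0), pos)
  mid <- findAnchors(pos, 0.6)
  expect_equal(mid$offset, c(3L, 12L))
  expect_equal(mid, pos[pos$matchScore >= 0.6, ])
})

test_that("WR score follows the windowed clustering formula exactly", {
  # anchor at offset 50 (score 1.0), suboptimals at offsets 40 and 60
  # (center distance 10 <= 25), one far hit at offset 90 (outside)
  pos <- posTable(c(40, 50, 60, 90), c(0.8, 1.0, 0.6, 0.9))
  N <- 50 - 5 + 1  # 46 windows fit in the clustering window
  expect_equal(wrScore(50L, pos, tSuboptimal = 0.5, windowNt = 50L),
               1.0 * (1 + (0.8 + 0.6) / N), tolerance = 1e-12)
  # isolated anchor: WR reduces to the match score
  expect_equal(wrScore(50L, posTable(50, 0.87), 0.5), 0.87)
  # below-threshold neighbors contribute nothing
  expect_equal(wrScore(50L, pos, tSuboptimal = 0.85), 1.0)
  # adding an in-window hit strictly increases WR; outside leaves it fixed
  more <- posTable(c(40, 50, 60, 70, 90), c(0.8, 1.0, 0.6, 0.7, 0.9))
  expect_gt(wrScore(50L, more, 0.5), wrScore(50L, pos, 0.5))
  far <- posTable(c(40, 50, 60, 90, 120), c(0.8, 1.0, 0.6, 0.9, 0.99))
  expect_equal(wrScore(50L, far, 0.5), wrScore(50L, pos, 0.5))
  # bounds: match(anchor) <= WR <= 2 * match(anchor), even when the window
  # is saturated with maximal suboptimals
  packed <- posTable(25:75, rep(1, 51))
  wrPacked <- wrScore(50L, packed, 0.5)
  expect_gte(wrPacked, 1)
  expect_lte(wrPacked, 2)
  expect_error(wrScore(999L, pos, 0.5), "not among")
})

test_that("WR is monotone in anchor and suboptimal scores", {
  base <- posTable(c(40, 50, 60), c(0.7, 0.9, 0.6))
  for (d in c(0.05, 0.1)) {
    upAnchor <- posTable(c(40, 50, 60), c(0.7, 0.9 + d, 0.6))
    upSub <- posTable(c(40, 50, 60), c(0.7 + d, 0.9, 0.6))
    expect_gte(wrScore(50L, upAnchor, 0.5), wrScore(50L, base, 0.5))
    expect_gte(wrScore(50L, upSub, 0.5), wrScore(50L, base, 0.5))
  }
})

test_that("z and one-tailed p follow the normal upper tail", {
  bg <- BackgroundModel("m", "internal_exon", sort(runif(1000)),
                        wrMean = 0.9, wrSd = 0.05, nWr = 500L)
  atMean <- zAndP(0.9, bg)
  expect_equal(atMean$z, 0)
  expect_equal(atMean$p, 0.5)
  z95 <- zAndP(0.9 + 1.6449 * 0.05, bg)
  expect_equal(z95$p, 0.05, tolerance = 1e-4)
  # quadrature oracle on the normal density
  for (wr in c(0.85, 0.92, 1.0, 1.1)) {
    res <- zAndP(wr, bg)
    quad <- stats::integrate(stats::dnorm, res$z, Inf,
                             rel.tol = 1e-12)$value
    expect_equal(res$p, quad, tolerance = 1e-8)
  }
})

test_that("site calling reports only significant, deduplicated sites", {
  m <- foxMotif()
  bg <- foxBackground()
  # planted consensus with two flanking 1-mismatch copies inside the window
  flank <- strrep("CA", 20)
  clustered <- paste0(flank, "UGCAUC", "CCCC", "UGCAUG", "CCCC", "UGCAUU",
                      flank)
  isolated <- paste0(flank, strrep("C", 6), "CCCC", "UGCAUG", "CCCC",
                     strrep("C", 6), flank)
  sClu <- callSites(clustered, m, backgrounds = bg)
  sIso <- callSites(isolated, m, backgrounds = bg)
  expect_true(50L %in% sClu$anchorOffset)   # the exact copy is called
  expect_true(all(sClu$p < 0.05))
  expect_true(all(sIso$p < 0.05))
  wrClu <- sClu$wrScore[sClu$anchorOffset == 50L]
  wrIso <- sIso$wrScore[sIso$anchorOffset == 50L]
  expect_gt(wrClu, wrIso)                   # clustering boosts WR
  expect_equal(wrIso, 1.0)                  # isolated anchor keeps its match
  # WR >= match score for every reported site
  expect_true(all(sClu$wrScore >= sClu$matchScore - 1e-12))
  # sites sorted by offset, deduplicated within k nt
  expect_true(all(diff(sClu$anchorOffset) >= 6L))
})

test_that("false anchors on null sequences stay near the nominal rate", {
  m <- foxMotif()
  bg <- foxBackground()
  tSig <- thresholdFor(bg, 0.005)
  set.seed(21)
  seqs <- randSeqs(100L, 250L, c(0.30, 0.20, 0.20, 0.30))
  nWin <- 0L
  nAnchor <- 0L
  for (s in seqs) {
    pos <- scanSequence(m, s)
    nWin <- nWin + nrow(pos)
    nAnchor <- nAnchor + sum(pos$matchScore >= tSig)
  }
  expected <- 0.005 * nWin
  expect_lte(nAnchor, expected + 4 * sqrt(expected))
})

test_that("prepending a plain flank shifts offsets without changing scores", {
  m <- foxMotif()
  bg <- foxBackground()
  set.seed(33)
  core <- paste0(strrep("CA", 30), "UGCAUG", strrep("UC", 30))
  flank <- strrep("A", 100)
  s1 <- callSites(core, m, backgrounds = bg)
  s2 <- callSites(paste0(flank, core), m, backgrounds = bg)
  expect_equal(s2$anchorOffset, s1$anchorOffset + 100L)
  expect_equal(s2$wrScore, s1$wrScore, tolerance = 1e-12)
  expect_equal(s2$p, s1$p, tolerance = 1e-12)
})

test_that("other-genome mode applies theoretical thresholds without z/p", {
  m <- foxMotif()
  seq <- paste0(strrep("CA", 20), "UGCAUG", strrep("UC", 20))
  s <- callSites(seq, m, mode = "other-genome")
  expect_gte(nrow(s), 1L)
  expect_true(all(is.na(s$p)))
  expect_true(all(s$wrScore >= s$wrCutoff))
  th <- theoreticalThreshold(m)
  expect_equal(unique(s$wrCutoff), th[["significant"]])
  # a degenerate all-uniform motif can never yield a site
  sN <- callSites(seq, parseIUPACConsensus("NNNNN", "n5"),
                  mode = "other-genome")
  expect_equal(nrow(sN), 0L)
})
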