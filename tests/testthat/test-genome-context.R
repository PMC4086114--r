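library(GenomicRanges)

# hand-built toy gene model: gene on chrA:2001-8000 with 5'UTR exon
# 2001-2200, internal exons 3001-3150 / 4001-4150, 3'UTR exon 7801-8000,
# plus an ncRNA at 9001-9500
toyAnnotation <- function() {
  RegionAnnotation(
    exons = GRanges("chrA", IRanges(c(3001, 4001), c(3150, 4150))),
    utr5Exons = GRanges("chrA", IRanges(2001, 2200)),
    utr3Exons = GRanges("chrA", IRanges(7801, 8000)),
    ncRNA = GRanges("chrA", IRanges(9001, 9500)),
    geneBounds = GRanges("chrA", IRanges(2001, 8000)))
}

probe <- function(pos, chrom = "chrA") GRanges(chrom, IRanges(pos, pos))

test_that("region classification matches the hand truth table", {
  ann <- toyAnnotation()
  cases <- list(
    list(pos = 3080, want = "internal_exon"),
    list(pos = 2100, want = "utr5_exon"),
    list(pos = 7900, want = "utr3_exon"),
    list(pos = 9200, want = "ncRNA"),
    list(pos = 3190, want = "splice_flank"),     # 40 nt from exon edge
    list(pos = 3600, want = "mid_intron_intergenic"),  # 450 nt from edges
    list(pos = 500,  want = "mid_intron_intergenic"),  # outside any gene
    list(pos = 15000, want = "mid_intron_intergenic"))
  got <- classifyRegion(ann,
    do.call(c, lapply(cases, function(cs) probe(cs$pos))))
  expect_identical(got, vapply(cases, `[[`, "", "want"))
  # flank threshold boundary: exactly 100 nt away is still a flank
  expect_identical(classifyRegion(ann, probe(3150 + 100)), "splice_flank")
  expect_identical(classifyRegion(ann, probe(3150 + 101)),
                   "mid_intron_intergenic")
})

test_that("classification is total, deterministic, and priority-ordered", {
  ann <- toyAnnotation()
  pts <- seq(100, 10000, by = 37)
  cls <- classifyRegion(ann, probe(pts))
  expect_length(cls, length(pts))
  expect_true(all(cls %in% regionClasses()))
  expect_identical(cls, classifyRegion(ann, probe(pts)))
  # ncRNA beats an overlapping exon annotation
  ann2 <- RegionAnnotation(
    exons = GRanges("chrA", IRanges(100, 200)),
    ncRNA = GRanges("chrA", IRanges(150, 250)),
    geneBounds = GRanges("chrA", IRanges(100, 300)))
  expect_identical(classifyRegion(ann2, probe(180)), "ncRNA")
  # unknown chromosome falls back to mid-intron/intergenic with a warning
  expect_warning(cls <- classifyRegion(ann, probe(100, "chrZ")), "absent")
  expect_identical(cls, "mid_intron_intergenic")
})

test_that("mean conservation matches direct averaging on sparse tracks", {
  # constant track over the environment
  tr <- ConservationTrack(rep("chrA", 100), 1001:1100, rep(0.7, 100))
  expect_equal(meanConservation(tr, "chrA", 1040, 1045), 0.7)
  # half zeros / half ones across the 50-nt environment around 1040-1045:
  # site width 6 -> environment 1018..1067
  tr2 <- ConservationTrack(rep("chrA", 100), 1001:1100,
                           rep(c(0, 1), each = 50))  # 0 until 1050
  env <- 1018:1067
  expect_equal(meanConservation(tr2, "chrA", 1040, 1045),
               mean(ifelse(env <= 1050, 0, 1)))
  # sparse coverage: brute-force oracle over covered positions
  set.seed(5)
  keep <- sort(sample(1001:1100, 60))
  tr3 <- ConservationTrack(rep("chrA", 60), keep, runif(60))
  covered <- keep[keep >= 1018 & keep <= 1067]
  oracle <- mean(tr3@score[match(covered, tr3@pos)])
  expect_equal(meanConservation(tr3, "chrA", 1040, 1045), oracle,
               tolerance = 1e-12)
  # under 50% coverage -> no-data
  tr4 <- ConservationTrack(rep("chrA", 10), 1018:1027, runif(10))
  expect_true(is.na(meanConservation(tr4, "chrA", 1040, 1045)))
  expect_true(is.na(meanConservation(tr4, "chrB", 1040, 1045)))
})

test_that("the intronic reference mean pools splice-flank coverage", {
  # single-exon gene with 100-nt flanks on both sides inside the gene
  ann <- RegionAnnotation(
    exons = GRanges("chrA", IRanges(1101, 1200)),
    geneBounds = GRanges("chrA", IRanges(1001, 1300)))
  # left flank 1001-1100 at 0.2, right flank 1201-1300 at 0.8
  tr <- ConservationTrack(rep("chrA", 300), 1001:1300,
                          c(rep(0.2, 100), rep(0.5, 100), rep(0.8, 100)))
  expect_equal(intronicReferenceMean(tr, ann), 0.5)
  trC <- ConservationTrack(rep("chrA", 300), 1001:1300, rep(0.42, 300))
  expect_equal(intronicReferenceMean(trC, ann), 0.42)
  # no coverage at all is a hard error
  trEmpty <- ConservationTrack("chrB", 5L, 1)
  expect_error(intronicReferenceMean(trEmpty, ann), "no conservation data")
})

test_that("conservation filtering removes only non-conserved intergenic sites", {
  mkSite <- function(id, cls, gstart, chrom = "chrA") {
    data.frame(seqId = id, anchorOffset = 0L, motifId = "m", protein = "P",
               kmer = "UGCAUG", matchScore = 1, wrScore = 1, z = 1,
               p = 0.01, wrCutoff = NA_real_, regionClass = cls,
               chrom = chrom, genomicStart = gstart,
               conservationPassed = NA, stringsAsFactors = FALSE)
  }
  # track: positions 1-200 at 0, positions 1001-1200 at 1
  tr <- ConservationTrack(rep("chrA", 400), c(1:200, 1001:1200),
                          c(rep(0, 200), rep(1, 200)))
  sites <- rbind(
    mkSite("exonLow", "internal_exon", 100),       # exempt class, kept
    mkSite("interLow", "mid_intron_intergenic", 100),   # 0 < 0.5, removed
    mkSite("interHigh", "mid_intron_intergenic", 1100), # 1 >= 0.5, kept
    mkSite("noData", "mid_intron_intergenic", 5000),    # uncovered, kept
    mkSite("noCoord", "mid_intron_intergenic", NA))     # unanchored, kept
  out <- conservationFilter(sites, tr, reference = 0.5)
  expect_identical(out$seqId,
                   c("exonLow", "interHigh", "noData", "noCoord"))
  expect_identical(out$conservationPassed[out$seqId == "interHigh"], TRUE)
  expect_true(is.na(out$conservationPassed[out$seqId == "exonLow"]))
  # tie at the reference is kept (strictly-below rule)
  trHalf <- ConservationTrack(rep("chrA", 200), 1:200, rep(0.5, 200))
  tied <- conservationFilter(mkSite("tie", "mid_intron_intergenic", 100),
                             trHalf, reference = 0.5)
  expect_equal(nrow(tied), 1L)
  # disabled filter is the identity
  expect_identical(conservationFilter(sites, tr, 0.5, enabled = FALSE),
                   sites)
  # raising the reference never increases the surviving set
  nKept <- vapply(c(0, 0.25, 0.5, 0.75, 1, 1.5), function(r)
    nrow(conservationFilter(sites, tr, r)), numeric(1L))
  expect_true(all(diff(nKept) <= 0))
})
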