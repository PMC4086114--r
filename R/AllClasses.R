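#' @import methods
#' @importFrom stats pnorm
#' @importFrom stats setNames
#' @importFrom utils head read.table write.table
#' @importClassesFrom GenomicRanges GRanges
NULL

RNA_BASES <- c("A", "C", "G", "U")
PROB_FLOOR <- 1e-3

#' Genomic region classes
#'
#' The six region classes used by the region-specific background model and
#' the conservation filter: non-coding RNA, 5'/3' UTR exons, internal exons,
#' intronic regions flanking splice sites, and mid-intron/intergenic
#' sequence. Classification priority follows this order.
#'
#' @return Character vector of the six class names, in priority order.
#' @export
#' @examples
#' regionClasses()
regionClasses <- function() {
  c("ncRNA", "utr5_exon", "utr3_exon", "internal_exon",
    "splice_flank", "mid_intron_intergenic")
}

# ---------------------------------------------------------------------------
# Motif

#' Motif: a binding motif as a probability matrix over A,C,G,U
#'
#' A position probability matrix of length \code{k} (3--30 nt), constructed
#' from an IUPAC consensus string or a MEME-format PSSM. Matrix entries are
#' floored at 1e-3 and columns renormalized so that log-odds scores stay
#' finite; the pre-flooring matrix is retained for information-content
#' calculations.
#'
#' @slot id Short unique identifier.
#' @slot protein Display name of the RBP the motif belongs to.
#' @slot probs 4 x k floored probability matrix, rows A,C,G,U.
#' @slot rawProbs 4 x k pre-flooring probability matrix.
#' @slot origin One of \code{"consensus"} or \code{"pssm"}.
#'
#' @seealso [parseIUPACConsensus()], [readMEMEMotifs()], [informationContent()]
#' @export
setClass("Motif", representation(
  id = "character",
  protein = "character",
  probs = "matrix",
  rawProbs = "matrix",
  origin = "character"
))

setValidity("Motif", function(object) {
  msgs <- character()
  p <- object@probs
  r <- object@rawProbs
  if (!identical(rownames(p), RNA_BASES))
    msgs <- c(msgs, "probs rows must be A,C,G,U")
  k <- ncol(p)
  if (k < 3L || k > 30L)
    msgs <- c(msgs, sprintf("motif length %d outside [3, 30]", k))
  if (!identical(dim(r), dim(p)))
    msgs <- c(msgs, "rawProbs and probs dimensions differ")
  if (any(r < 0))
    msgs <- c(msgs, "negative probabilities")
  if (any(abs(colSums(p) - 1) > 1e-6))
    msgs <- c(msgs, "floored columns must sum to 1 within 1e-6")
  if (any(abs(colSums(r) - 1) > 1e-6))
    msgs <- c(msgs, "raw columns must sum to 1 within 1e-6")
  # flooring precedes column renormalization, which shrinks entries by at
  # most the added floor mass (< 0.4% for 4 rows)
  if (any(p < PROB_FLOOR * 0.99))
    msgs <- c(msgs, "floored entries must be >= 1e-3 (pre-renormalization)")
  if (!object@origin %in% c("consensus", "pssm"))
    msgs <- c(msgs, "origin must be 'consensus' or 'pssm'")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Motif construct a Motif from a raw (possibly zero-containing)
#'   probability matrix; flooring and renormalization are applied.
#' @param id,protein,origin see slots.
#' @param matrix 4 x k numeric matrix (rows A,C,G,U or unnamed in that
#'   order), columns summing to 1.
#' @export
Motif <- function(id, matrix, protein = id, origin = "pssm") {
  m <- as.matrix(matrix)
  if (nrow(m) != 4L)
    stop("motif matrix must have 4 rows (A, C, G, U)")
  dimnames(m) <- list(RNA_BASES, NULL)
  floored <- pmax(m, PROB_FLOOR)
  floored <- sweep(floored, 2L, colSums(floored), "/")
  new("Motif", id = id, protein = protein, probs = floored,
      rawProbs = m, origin = origin)
}

#' @describeIn Motif motif identifier.
#' @param x,object a Motif.
#' @export
motifId <- function(x) x@id

#' @describeIn Motif protein display name.
#' @export
motifProtein <- function(x) x@protein

#' @describeIn Motif motif length k (window size).
#' @export
motifLength <- function(x) ncol(x@probs)

#' @describeIn Motif floored 4 x k probability matrix.
#' @export
motifMatrix <- function(x) x@probs

#' @describeIn Motif pre-flooring probability matrix.
#' @export
motifRawMatrix <- function(x) x@rawProbs

#' @describeIn Motif the single best k-mer (column-wise argmax).
#' @export
bestKmer <- function(x) {
  paste(RNA_BASES[apply(x@probs, 2L, which.max)], collapse = "")
}

setMethod("show", "Motif", function(object) {
  cat(sprintf("Motif '%s' (%s), k = %d, origin = %s\n",
              object@id, object@protein, motifLength(object), object@origin))
  cat(sprintf("  consensus (argmax): %s, IC = %.2f bits\n",
              bestKmer(object), informationContent(object)))
})

# ---------------------------------------------------------------------------
# StringencyLevel

#' StringencyLevel: anchor and suboptimal p-value thresholds
#'
#' The three search stringency tiers. The significant threshold calls anchor
#' sites; the suboptimal threshold admits secondary matches into the WR
#' clustering window.
#'
#' @slot name One of \code{"high"}, \code{"medium"}, \code{"low"}.
#' @slot pSignificant Anchor match p-value threshold.
#' @slot pSuboptimal Suboptimal match p-value threshold.
#' @export
setClass("StringencyLevel", representation(
  name = "character",
  pSignificant = "numeric",
  pSuboptimal = "numeric"
))

setValidity("StringencyLevel", function(object) {
  if (object@pSignificant > object@pSuboptimal)
    return("pSignificant must be <= pSuboptimal")
  TRUE
})

#' @describeIn StringencyLevel constructor by tier name: high = (0.001,
#'   0.01), medium = (0.005, 0.01) (the default tier), low = (0.01, 0.02).
#' @param name tier name.
#' @export
#' @examples
#' stringencyLevel("medium")
stringencyLevel <- function(name = c("medium", "high", "low")) {
  name <- match.arg(name)
  p <- switch(name,
    high   = c(0.001, 0.01),
    medium = c(0.005, 0.01),
    low    = c(0.01, 0.02))
  new("StringencyLevel", name = name, pSignificant = p[1], pSuboptimal = p[2])
}

#' @describeIn StringencyLevel anchor (significant) p-value threshold.
#' @param x a StringencyLevel.
#' @export
pSignificant <- function(x) x@pSignificant

#' @describeIn StringencyLevel suboptimal p-value threshold.
#' @export
pSuboptimal <- function(x) x@pSuboptimal

setMethod("show", "StringencyLevel", function(object) {
  cat(sprintf("StringencyLevel '%s': p_significant < %g, p_suboptimal < %g\n",
              object@name, object@pSignificant, object@pSuboptimal))
})

# ---------------------------------------------------------------------------
# BackgroundModel

#' BackgroundModel: per-motif, per-region empirical score background
#'
#' Holds the sorted sample of background match scores (used for empirical
#' match p-values and anchor/suboptimal score thresholds) and the mean and
#' standard deviation of background WR scores (used for the Z-score of
#' candidate sites), for one motif in one genomic region class.
#'
#' @slot motifId Motif the background was built for.
#' @slot regionClass One of [regionClasses()].
#' @slot matchScores Sorted ascending background match-score sample
#'   (n >= 1000).
#' @slot wrMean,wrSd Mean and sd of background WR scores (sd > 0).
#' @slot nWr WR sample size (>= 200).
#' @seealso [buildBackground()], [empiricalPvalue()], [thresholdFor()]
#' @export
setClass("BackgroundModel", representation(
  motifId = "character",
  regionClass = "character",
  matchScores = "numeric",
  wrMean = "numeric",
  wrSd = "numeric",
  nWr = "integer"
))

setValidity("BackgroundModel", function(object) {
  msgs <- character()
  if (length(object@matchScores) < 1000L)
    msgs <- c(msgs, "match-score sample must have n >= 1000")
  if (is.unsorted(object@matchScores))
    msgs <- c(msgs, "match-score sample must be sorted ascending")
  if (object@nWr < 200L)
    msgs <- c(msgs, "WR sample must have n >= 200")
  if (!(object@wrSd > 0))
    msgs <- c(msgs, "WR sd must be > 0 (degenerate background)")
  if (!object@regionClass %in% regionClasses())
    msgs <- c(msgs, "unknown region class")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn BackgroundModel direct constructor (mostly for tests and
#'   deserialization); [buildBackground()] is the standard builder.
#' @param motifId,regionClass,matchScores,wrMean,wrSd,nWr see slots.
#' @export
BackgroundModel <- function(motifId, regionClass, matchScores, wrMean,
                            wrSd, nWr) {
  new("BackgroundModel", motifId = motifId, regionClass = regionClass,
      matchScores = sort(as.numeric(matchScores)), wrMean = wrMean,
      wrSd = wrSd, nWr = as.integer(nWr))
}

#' @describeIn BackgroundModel number of background match scores.
#' @param x a BackgroundModel.
#' @export
nMatch <- function(x) length(x@matchScores)

#' @describeIn BackgroundModel sorted background match-score sample.
#' @export
matchScores <- function(x) x@matchScores

#' @describeIn BackgroundModel mean background WR score.
#' @export
wrMean <- function(x) x@wrMean

#' @describeIn BackgroundModel sd of background WR scores.
#' @export
wrSd <- function(x) x@wrSd

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf(
    "BackgroundModel: motif '%s', region '%s'\n  n_match = %d, WR mean = %.4f, WR sd = %.4f (n_wr = %d)\n",
    object@motifId, object@regionClass, nMatch(object),
    object@wrMean, object@wrSd, object@nWr))
})

# ---------------------------------------------------------------------------
# ScoreDistribution

#' ScoreDistribution: exact match-score distribution of a random k-mer
#'
#' The distribution of the normalized match score of a motif over iid random
#' k-mers, computed by per-column convolution on a discretized raw-score
#' grid. Used for the theoretical (other-genome) thresholds.
#'
#' @slot motifId Motif the distribution belongs to.
#' @slot score Sorted support (normalized match scores in [0, 1]).
#' @slot prob Probability mass per support point (sums to 1).
#' @slot bin Raw-score discretization bin width.
#' @seealso [analyticScoreDistribution()], [theoreticalThreshold()]
#' @export
setClass("ScoreDistribution", representation(
  motifId = "character",
  score = "numeric",
  prob = "numeric",
  bin = "numeric"
))

setValidity("ScoreDistribution", function(object) {
  msgs <- character()
  if (length(object@score) != length(object@prob))
    msgs <- c(msgs, "score and prob lengths differ")
  if (is.unsorted(object@score))
    msgs <- c(msgs, "support must be sorted")
  if (abs(sum(object@prob) - 1) > 1e-9)
    msgs <- c(msgs, "probabilities must sum to 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ScoreDistribution", function(object) {
  cat(sprintf(
    "ScoreDistribution for motif '%s': %d support points, bin = %g\n",
    object@motifId, length(object@score), object@bin))
})

# ---------------------------------------------------------------------------
# RegionAnnotation

#' RegionAnnotation: interval sets defining the six region classes
#'
#' Gene-model interval sets (as \link[GenomicRanges]{GRanges}) from which
#' any genomic position is classified into one of [regionClasses()].
#' Interval sets are reduced (merged and sorted) on construction.
#'
#' @slot exons Internal (coding) exons.
#' @slot utr5Exons,utr3Exons UTR exons.
#' @slot ncRNA Non-coding RNA gene intervals.
#' @slot geneBounds Whole-gene spans (anything outside is intergenic).
#' @seealso [classifyRegion()]
#' @export
setClass("RegionAnnotation", representation(
  exons = "GRanges",
  utr5Exons = "GRanges",
  utr3Exons = "GRanges",
  ncRNA = "GRanges",
  geneBounds = "GRanges"
))

#' @describeIn RegionAnnotation constructor; each argument is a GRanges
#'   (possibly empty), merged and sorted on construction.
#' @param exons,utr5Exons,utr3Exons,ncRNA,geneBounds GRanges interval sets.
#' @export
RegionAnnotation <- function(exons = GenomicRanges::GRanges(),
                             utr5Exons = GenomicRanges::GRanges(),
                             utr3Exons = GenomicRanges::GRanges(),
                             ncRNA = GenomicRanges::GRanges(),
                             geneBounds = GenomicRanges::GRanges()) {
  tidy <- function(gr) sort(GenomicRanges::reduce(gr, ignore.strand = TRUE))
  new("RegionAnnotation", exons = tidy(exons), utr5Exons = tidy(utr5Exons),
      utr3Exons = tidy(utr3Exons), ncRNA = tidy(ncRNA),
      geneBounds = tidy(geneBounds))
}

setMethod("show", "RegionAnnotation", function(object) {
  cat(sprintf(
    "RegionAnnotation: %d exons, %d 5'UTR, %d 3'UTR, %d ncRNA, %d genes\n",
    length(object@exons), length(object@utr5Exons),
    length(object@utr3Exons), length(object@ncRNA),
    length(object@geneBounds)))
})

# ---------------------------------------------------------------------------
# ConservationTrack

#' ConservationTrack: sparse per-base conservation scores
#'
#' A sparse position-to-score map with phyloP/phastCons semantics; coverage
#' may be partial (assembly gaps, unscored bases). Positions are 1-based and
#' strictly increasing within each chromosome.
#'
#' @slot chrom Chromosome per scored base.
#' @slot pos 1-based position per scored base.
#' @slot score Conservation score per base.
#' @seealso [readBedGraphTrack()], [readWiggleTrack()], [meanConservation()]
#' @export
setClass("ConservationTrack", representation(
  chrom = "character",
  pos = "integer",
  score = "numeric"
))

setValidity("ConservationTrack", function(object) {
  n <- length(object@pos)
  if (length(object@chrom) != n || length(object@score) != n)
    return("chrom, pos, score must have equal length")
  for (ch in unique(object@chrom)) {
    p <- object@pos[object@chrom == ch]
    if (any(diff(p) <= 0L))
      return(sprintf("positions not strictly increasing on %s", ch))
  }
  TRUE
})

#' @describeIn ConservationTrack constructor; rows are sorted by chromosome
#'   then position, duplicate positions are an error.
#' @param chrom,pos,score parallel vectors of scored bases.
#' @export
ConservationTrack <- function(chrom, pos, score) {
  o <- order(chrom, pos)
  new("ConservationTrack", chrom = as.character(chrom)[o],
      pos = as.integer(pos)[o], score = as.numeric(score)[o])
}

setMethod("show", "ConservationTrack", function(object) {
  cat(sprintf("ConservationTrack: %d scored bases on %d chromosome(s)\n",
              length(object@pos), length(unique(object@chrom))))
})

# ---------------------------------------------------------------------------
# ContingencyTable

#' ContingencyTable: strong/weak motif-detection 2x2 table
#'
#' Counts of sequences with (\code{a}, \code{c}) and without (\code{b},
#' \code{d}) at least one predicted binding site, in the strong-binder and
#' weak-binder sets respectively.
#'
#' @slot a Strong sequences with >= 1 site.
#' @slot b Strong sequences without.
#' @slot c Weak sequences with >= 1 site.
#' @slot d Weak sequences without.
#' @seealso [tabulateHits()], [fisherOneTailed()], [sensitivitySpecificity()]
#' @export
setClass("ContingencyTable", representation(
  a = "integer", b = "integer", c = "integer", d = "integer"
))

setValidity("ContingencyTable", function(object) {
  if (any(c(object@a, object@b, object@c, object@d) < 0L))
    return("all counts must be >= 0")
  TRUE
})

#' @describeIn ContingencyTable constructor.
#' @param a,b,c,d cell counts.
#' @export
ContingencyTable <- function(a, b, c, d) {
  new("ContingencyTable", a = as.integer(a), b = as.integer(b),
      c = as.integer(c), d = as.integer(d))
}

setMethod("show", "ContingencyTable", function(object) {
  m <- matrix(c(object@a, object@b, object@c, object@d), 2L, 2L,
              byrow = TRUE,
              dimnames = list(c("strong", "weak"), c("hit", "no hit")))
  cat("ContingencyTable:\n")
  print(m)
})
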