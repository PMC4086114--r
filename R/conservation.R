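# Conservation tracks and the mid-intron/intergenic conservation filter.

.expandTrack <- function(gr) {
  if (!length(gr)) return(ConservationTrack(character(), integer(), numeric()))
  w <- GenomicRanges::width(gr)
  ConservationTrack(
    chrom = rep(as.character(GenomeInfoDb::seqnames(gr)), w),
    pos = unlist(lapply(seq_along(gr), function(i)
      seq.int(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])),
      use.names = FALSE),
    score = rep(S4Vectors::mcols(gr)$score, w))
}

#' Read a conservation track from a bedGraph file
#'
#' Intervals are expanded to per-base scores (bedGraph is 0-based
#' half-open; stored positions are 1-based).
#'
#' @param file bedGraph path.
#' @return A [ConservationTrack-class].
#' @export
readBedGraphTrack <- function(file) {
  .expandTrack(rtracklayer::import(file, format = "bedGraph"))
}

#' Read a conservation track from a fixedStep/variableStep wiggle file
#'
#' @param file Wiggle path.
#' @return A [ConservationTrack-class].
#' @export
readWiggleTrack <- function(file) {
  .expandTrack(rtracklayer::import(file, format = "wig"))
}

# Indices into the track for chrom positions [from, to]; empty when chrom
# absent.
.trackSlice <- function(track, chrom, from, to) {
  sel <- which(track@chrom == chrom)
  if (!length(sel)) return(integer())
  p <- track@pos[sel]
  lo <- findInterval(from - 1L, p) + 1L
  hi <- findInterval(to, p)
  if (hi < lo) return(integer())
  sel[lo:hi]
}

#' Mean conservation of a site's environment
#'
#' The environment is the site interval extended symmetrically to
#' \code{environmentNt} total width (default 50 nt, matching the WR
#' window). Returns the arithmetic mean of the track over covered
#' positions, or \code{NA} (no-data) when fewer than half of the
#' environment positions carry a score.
#'
#' @param track A [ConservationTrack-class].
#' @param chrom Chromosome.
#' @param start,end 1-based inclusive site interval.
#' @param environmentNt Environment width in nt.
#' @return Mean conservation, or \code{NA_real_} for insufficient coverage.
#' @export
meanConservation <- function(track, chrom, start, end,
                             environmentNt = 50L) {
  w <- end - start + 1L
  envW <- max(w, environmentNt)
  extra <- envW - w
  from <- start - extra %/% 2L
  to <- from + envW - 1L
  idx <- .trackSlice(track, chrom, from, to)
  if (length(idx) < envW / 2) return(NA_real_)
  mean(track@score[idx])
}

#' Reference conservation level of intronic regulatory regions
#'
#' The pooled mean conservation over all splice-flank positions (intronic
#' bases within \code{flankNt} of an exon edge) that carry track data. This
#' is the reference against which mid-intron/intergenic sites are filtered.
#'
#' @param track A [ConservationTrack-class].
#' @param annotation A [RegionAnnotation-class].
#' @param flankNt Splice-flank width in nt.
#' @return Mean conservation of intronic regulatory regions.
#' @export
intronicReferenceMean <- function(track, annotation, flankNt = 100L) {
  fl <- .spliceFlankRegions(annotation, flankNt)
  idx <- unlist(lapply(seq_along(fl), function(i)
    .trackSlice(track, as.character(GenomeInfoDb::seqnames(fl))[i],
                GenomicRanges::start(fl)[i], GenomicRanges::end(fl)[i])),
    use.names = FALSE)
  if (!length(idx))
    stop("no conservation data over intronic regulatory regions; disable the conservation filter")
  mean(track@score[idx])
}

#' Conservation-based filtering of binding sites
#'
#' Applied only to sites in the mid-intron/intergenic class: such a site is
#' removed iff the mean conservation of its environment is strictly below
#' the intronic reference level. Sites in any other region class, sites
#' without conservation data (or without genomic coordinates), and all
#' sites when \code{enabled = FALSE} are kept. When enabled, the
#' \code{conservationPassed} column records the decision (NA where the
#' filter does not apply); when disabled the input is returned unchanged.
#'
#' @param sites Binding-site data.frame from [callSites()] with genomic
#'   coordinates filled in.
#' @param track A [ConservationTrack-class].
#' @param reference Reference mean from [intronicReferenceMean()].
#' @param enabled Apply the filter? (Users may deliberately skip it.)
#' @param environmentNt Environment width for [meanConservation()].
#' @return The surviving sites.
#' @export
conservationFilter <- function(sites, track, reference, enabled = TRUE,
                               environmentNt = 50L) {
  if (!enabled || !nrow(sites)) return(sites)
  passed <- rep(NA, nrow(sites))
  target <- which(sites$regionClass %in% "mid_intron_intergenic" &
                  !is.na(sites$chrom) & !is.na(sites$genomicStart))
  for (i in target) {
    k <- nchar(sites$kmer[i])
    m <- meanConservation(track, sites$chrom[i], sites$genomicStart[i],
                          sites$genomicStart[i] + k - 1L, environmentNt)
    if (!is.na(m)) passed[i] <- m >= reference
  }
  sites$conservationPassed <- passed
  keep <- is.na(passed) | passed
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
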