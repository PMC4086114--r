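# Genomic region classification against a RegionAnnotation.

#' Classify genomic positions into the six region classes
#'
#' Classification uses the midpoint of each site interval, with priority
#' ncRNA > 5'UTR exon > 3'UTR exon > internal exon > splice flank >
#' mid-intron/intergenic. A splice flank is an intronic midpoint (inside a
#' gene, outside all exons) within \code{flankNt} of an annotated exon
#' edge. Positions outside every gene, and positions on chromosomes absent
#' from the annotation (with a warning), are mid-intron/intergenic.
#'
#' @param annotation A [RegionAnnotation-class].
#' @param sites A \link[GenomicRanges]{GRanges} of site intervals (1-based).
#' @param flankNt Splice-flank width in nt.
#' @return Character vector of classes, one per site.
#' @export
classifyRegion <- function(annotation, sites, flankNt = 100L) {
  n <- length(sites)
  if (!n) return(character())
  mid <- GenomicRanges::resize(sites, width = 1L, fix = "center")
  GenomicRanges::strand(mid) <- "*"
  knownChroms <- unique(unlist(lapply(
    list(annotation@exons, annotation@utr5Exons, annotation@utr3Exons,
         annotation@ncRNA, annotation@geneBounds),
    function(gr) as.character(GenomeInfoDb::seqnames(gr)))))
  unknown <- !as.character(GenomeInfoDb::seqnames(mid)) %in% knownChroms
  if (any(unknown))
    warning(sprintf(
      "%d site(s) on chromosome(s) absent from the annotation; classified as mid_intron_intergenic",
      sum(unknown)))
  # seqlevel-mismatch warnings are expected here: unknown chromosomes are
  # handled explicitly above
  hits <- function(gr) {
    if (!length(gr)) rep(FALSE, n)
    else suppressWarnings(
      GenomicRanges::countOverlaps(mid, gr, ignore.strand = TRUE) > 0L)
  }
  cls <- rep("mid_intron_intergenic", n)
  allExons <- c(annotation@exons, annotation@utr5Exons,
                annotation@utr3Exons)
  inGene <- hits(annotation@geneBounds)
  if (length(allExons)) {
    d <- suppressWarnings(
      GenomicRanges::distanceToNearest(mid, allExons, ignore.strand = TRUE))
    near <- rep(FALSE, n)
    # gap semantics: the base adjacent to an exon edge has distance 0, so
    # the flank covers the flankNt closest intronic bases (gap < flankNt)
    near[S4Vectors::queryHits(d)] <-
      S4Vectors::mcols(d)$distance < flankNt
    cls[inGene & near] <- "splice_flank"
  }
  cls[hits(annotation@exons)] <- "internal_exon"
  cls[hits(annotation@utr3Exons)] <- "utr3_exon"
  cls[hits(annotation@utr5Exons)] <- "utr5_exon"
  cls[hits(annotation@ncRNA)] <- "ncRNA"
  cls[unknown] <- "mid_intron_intergenic"
  cls
}

# Intronic splice-flank intervals implied by an annotation: flankNt on each
# side of every exon edge, clipped to gene bounds and excluding exons.
.spliceFlankRegions <- function(annotation, flankNt = 100L) {
  allExons <- GenomicRanges::reduce(
    c(annotation@exons, annotation@utr5Exons, annotation@utr3Exons),
    ignore.strand = TRUE)
  if (!length(allExons)) return(GenomicRanges::GRanges())
  left <- GenomicRanges::flank(allExons, flankNt, start = TRUE,
                               ignore.strand = TRUE)
  right <- GenomicRanges::flank(allExons, flankNt, start = FALSE,
                                ignore.strand = TRUE)
  fl <- GenomicRanges::reduce(c(left, right), ignore.strand = TRUE)
  fl <- GenomicRanges::intersect(fl, annotation@geneBounds,
                                 ignore.strand = TRUE)
  GenomicRanges::setdiff(fl, allExons, ignore.strand = TRUE)
}
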