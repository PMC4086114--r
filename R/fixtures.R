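# Seeded synthetic fixture generator: background region sets, strong/weak
# binder sets with planted motif copies, a toy gene model exercising all six
# region classes, and a toy conservation track. Every fixture carries its
# ground-truth manifest.

# Base composition (A, C, G, U) emulated per region class: exonic classes
# slightly GC-enriched, UTR3/intronic classes AU-enriched, ncRNA uniform.
FIXTURE_BASE_FREQS <- list(
  ncRNA = c(0.25, 0.25, 0.25, 0.25),
  utr5_exon = c(0.20, 0.30, 0.30, 0.20),
  utr3_exon = c(0.32, 0.18, 0.18, 0.32),
  internal_exon = c(0.24, 0.26, 0.26, 0.24),
  splice_flank = c(0.28, 0.22, 0.22, 0.28),
  mid_intron_intergenic = c(0.30, 0.20, 0.20, 0.30))

.randSeqs <- function(n, len, freqs) {
  if (n == 0L) return(character())
  chars <- sample(RNA_BASES, n * len, replace = TRUE, prob = freqs)
  all <- paste(chars, collapse = "")
  substring(all, seq(1L, by = len, length.out = n),
            seq(len, by = len, length.out = n))
}

.mutateOne <- function(kmer, col) {
  b <- substr(kmer, col, col)
  repl <- sample(setdiff(RNA_BASES, b), 1L)
  substr(kmer, col, col) <- repl
  kmer
}

# Replace any exact consensus occurrence outside `allowed` 1-based starts by
# mutating one window base that does not fall inside an allowed copy;
# repeats until clean.
.scrubExactCopies <- function(seq, consensus, allowed) {
  k <- nchar(consensus)
  protected <- unlist(lapply(allowed, function(a) a:(a + k - 1L)))
  repeat {
    wins <- substring(seq, seq_len(nchar(seq) - k + 1L), k:nchar(seq))
    hits <- setdiff(which(wins == consensus), allowed)
    if (!length(hits)) return(seq)
    for (h in hits) {
      free <- setdiff(h:(h + k - 1L), protected)
      if (!length(free)) next  # fully inside an allowed copy: impossible
      pos <- free[ceiling(length(free) / 2)]
      col <- pos - h + 1L
      substr(seq, pos, pos) <- sample(
        setdiff(RNA_BASES, substr(consensus, col, col)), 1L)
    }
  }
}

#' Generate the seeded synthetic fixture bundle
#'
#' Produces, deterministically for a given seed: (a) background sequence
#' sets per region class drawn iid from per-class base compositions;
#' (b) a "strong binder" set in which a fraction \code{plantRate} of the
#' sequences carries one exact copy of the motif consensus flanked by
#' \code{nSuboptimal} single-mismatch copies within the 50-nt clustering
#' window, and a "weak binder" set without planted copies; (c) a toy gene
#' model on chromosome \code{chrT} exercising all six region classes, with
#' strong and weak binder loci laid out in intergenic space; (d) a toy
#' conservation track scoring splice flanks at 0.5, strong-binder loci at
#' 0.8 and weak-binder loci at 0.1. Exact consensus copies arising by
#' chance in strong-binder flanks are scrubbed so the manifest is the
#' complete truth for score-1.0 matches.
#'
#' @param m A [Motif-class]; its consensus (column-wise argmax) is planted.
#' @param seed Integer seed; regeneration with the same seed is
#'   byte-identical.
#' @param nBackground,backgroundLength Background set size and sequence
#'   length per region class.
#' @param backgroundClasses Region classes to generate backgrounds for.
#' @param nStrong,nWeak Binder-set sizes.
#' @param binderLength Binder sequence length (nt).
#' @param plantRate Probability a strong sequence receives a planted site.
#' @param nSuboptimal Single-mismatch copies planted around each anchor.
#' @return List with \code{background} (named list of character vectors),
#'   \code{strong}/\code{weak} (query-record data.frames with genomic
#'   anchors on \code{chrT}), \code{annotation}
#'   ([RegionAnnotation-class]), \code{track}
#'   ([ConservationTrack-class]), \code{manifest} (per-sequence ground
#'   truth) and \code{genome} (chromosome metadata).
#' @export
generateFixtures <- function(m, seed = 1L, nBackground = 1000L,
                             backgroundLength = 250L,
                             backgroundClasses = regionClasses(),
                             nStrong = 500L, nWeak = 500L,
                             binderLength = 120L, plantRate = 0.8,
                             nSuboptimal = 2L) {
  stopifnot(plantRate >= 0, plantRate <= 1, binderLength >= 60L)
  set.seed(seed)
  k <- motifLength(m)
  consensus <- bestKmer(m)

  background <- lapply(setNames(nm = backgroundClasses), function(cl)
    .randSeqs(nBackground, backgroundLength, FIXTURE_BASE_FREQS[[cl]]))

  # toy gene model on chrT
  annotation <- RegionAnnotation(
    exons = GenomicRanges::GRanges("chrT", IRanges::IRanges(
      c(3001, 4001, 5001), c(3150, 4150, 5150))),
    utr5Exons = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(2001, 2200)),
    utr3Exons = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(7801, 8000)),
    ncRNA = GenomicRanges::GRanges("chrT", IRanges::IRanges(9001, 9500)),
    geneBounds = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(2001, 8000)))

  stride <- binderLength + 80L
  strongBase <- 12000L
  weakBase <- strongBase + nStrong * stride + 2000L
  chromLen <- weakBase + nWeak * stride + 2000L

  plantOne <- function(seqStr) {
    anchor <- sample(30:(binderLength - k - 25L), 1L)
    substr(seqStr, anchor, anchor + k - 1L) <- consensus
    subs <- integer()
    if (nSuboptimal > 0L) {
      # non-overlapping slots with k-mer centers within the 50-nt window
      slots <- c(k + 1L, 2L * (k + 1L), -(k + 1L), -2L * (k + 1L))
      slots <- slots[abs(slots) <= 25L]
      deltas <- sample(slots, min(nSuboptimal, length(slots)))
      for (d in deltas) {
        p <- anchor + d
        if (p < 1L || p + k - 1L > binderLength) next
        copy <- .mutateOne(consensus, sample(k, 1L))
        substr(seqStr, p, p + k - 1L) <- copy
        subs <- c(subs, p)
      }
    }
    list(seq = .scrubExactCopies(seqStr, consensus, anchor),
         anchor = anchor, subs = sort(subs))
  }

  makeSet <- function(n, setName, base) {
    if (n == 0L)
      return(list(
        records = .emptyRecords(),
        manifest = data.frame(id = character(), set = character(),
                              planted = logical(),
                              anchorStart = integer(),
                              suboptStarts = character(),
                              stringsAsFactors = FALSE)))
    seqs <- .randSeqs(n, binderLength, FIXTURE_BASE_FREQS$mid_intron_intergenic)
    planted <- if (setName == "strong") runif(n) < plantRate
               else rep(FALSE, n)
    anchorPos <- rep(NA_integer_, n)
    subPos <- rep("", n)
    for (i in which(planted)) {
      pl <- plantOne(seqs[i])
      seqs[i] <- pl$seq
      anchorPos[i] <- pl$anchor
      subPos[i] <- paste(pl$subs, collapse = ",")
    }
    gstart <- base + (seq_len(n) - 1L) * stride + 1L
    rec <- data.frame(
      id = sprintf("%s_%04d", setName, seq_len(n)), sequence = seqs,
      chrom = "chrT", gstart = gstart, gend = gstart + binderLength - 1L,
      strand = "+", source = "coordinates", stringsAsFactors = FALSE)
    man <- data.frame(id = rec$id, set = setName, planted = planted,
                      anchorStart = anchorPos, suboptStarts = subPos,
                      stringsAsFactors = FALSE)
    list(records = rec, manifest = man)
  }

  strong <- makeSet(nStrong, "strong", strongBase)
  weak <- makeSet(nWeak, "weak", weakBase)

  # toy conservation track: splice flanks 0.5, strong loci 0.8, weak 0.1
  fl <- .spliceFlankRegions(annotation, 100L)
  trackPos <- integer()
  trackScore <- numeric()
  addRegion <- function(from, to, value) {
    p <- seq.int(from, to)
    trackPos <<- c(trackPos, p)
    trackScore <<- c(trackScore, rep(value, length(p)))
  }
  for (i in seq_along(fl))
    addRegion(GenomicRanges::start(fl)[i], GenomicRanges::end(fl)[i], 0.5)
  pad <- 30L
  for (i in seq_len(nStrong))
    addRegion(strong$records$gstart[i] - pad,
              strong$records$gend[i] + pad, 0.8)
  for (i in seq_len(nWeak))
    addRegion(weak$records$gstart[i] - pad,
              weak$records$gend[i] + pad, 0.1)
  track <- ConservationTrack(rep("chrT", length(trackPos)), trackPos,
                             trackScore)

  list(background = background, strong = strong$records,
       weak = weak$records, annotation = annotation, track = track,
       manifest = rbind(strong$manifest, weak$manifest),
       genome = list(chrom = "chrT", length = chromLen),
       params = list(seed = seed, motifId = motifId(m),
                     consensus = consensus, nBackground = nBackground,
                     backgroundLength = backgroundLength,
                     nStrong = nStrong, nWeak = nWeak,
                     binderLength = binderLength, plantRate = plantRate,
                     nSuboptimal = nSuboptimal))
}

#' Write a fixture bundle to plain-text files
#'
#' Backgrounds and binder sets as FASTA, binder coordinates as BED, the
#' gene model as BED files per feature type, the conservation track as
#' bedGraph, and the manifest as TSV.
#'
#' @param bundle List from [generateFixtures()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeFixtures <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- function(ids, seqs, path) {
    writeLines(paste0(">", ids, "\n", seqs), path)
  }
  for (cl in names(bundle$background))
    fasta(sprintf("%s_%04d", cl, seq_along(bundle$background[[cl]])),
          bundle$background[[cl]],
          file.path(dir, sprintf("background_%s.fa", cl)))
  for (set in c("strong", "weak")) {
    rec <- bundle[[set]]
    fasta(rec$id, rec$sequence, file.path(dir, paste0(set, ".fa")))
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", rec$chrom,
                       rec$gstart - 1L, rec$gend, rec$id, rec$strand),
               file.path(dir, paste0(set, ".bed")))
  }
  ann <- bundle$annotation
  bed <- function(gr, path) {
    writeLines(sprintf("chrT\t%d\t%d",
                       GenomicRanges::start(gr) - 1L,
                       GenomicRanges::end(gr)), path)
  }
  bed(ann@exons, file.path(dir, "annotation_exons.bed"))
  bed(ann@utr5Exons, file.path(dir, "annotation_utr5.bed"))
  bed(ann@utr3Exons, file.path(dir, "annotation_utr3.bed"))
  bed(ann@ncRNA, file.path(dir, "annotation_ncrna.bed"))
  bed(ann@geneBounds, file.path(dir, "annotation_genes.bed"))
  tr <- bundle$track
  writeLines(sprintf("%s\t%d\t%d\t%s", tr@chrom, tr@pos - 1L, tr@pos,
                     .fmtNum(tr@score)),
             file.path(dir, "conservation.bedGraph"))
  write.table(bundle$manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
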