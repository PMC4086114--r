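# Weighted-Rank (WR) scoring: clustering-aware re-scoring of anchor sites.

# Vectorized WR over anchor indices. offsets sorted ascending; eligibility
# of suboptimal neighbors is score >= tSub; window is measured center-to-
# center (+-windowNt/2). The clustering boost sum(match)/N is capped at 1 so
# that match(anchor) <= WR <= 2*match(anchor) always holds.
.wrScores <- function(offsets, scores, anchorIdx, tSub, windowNt = 50L, k) {
  if (!length(anchorIdx)) return(numeric())
  centers <- offsets + k / 2
  elig <- scores >= tSub
  cs <- c(0, cumsum(scores * elig))
  half <- windowNt / 2 + 1e-9
  lo <- findInterval(centers[anchorIdx] - half, centers) + 1L
  hi <- findInterval(centers[anchorIdx] + half, centers)
  inWin <- cs[hi + 1L] - cs[lo]
  own <- scores[anchorIdx] * elig[anchorIdx]
  N <- windowNt - k + 1
  boost <- pmin(1, (inWin - own) / N)
  scores[anchorIdx] * (1 + boost)
}

#' Filter scored positions down to significant anchors
#'
#' @param positions data.frame from [scanSequence()], sorted by offset.
#' @param tSignificant Match-score threshold for anchor sites.
#' @return The subset with \code{matchScore >= tSignificant}, order
#'   preserved.
#' @export
findAnchors <- function(positions, tSignificant) {
  positions[positions$matchScore >= tSignificant, , drop = FALSE]
}

#' Weighted-Rank score of one anchor
#'
#' Measures the propensity of suboptimal matches to cluster around a
#' significant anchor within a window of \code{windowNt} (default 50) nt.
#' With k-mer centers \eqn{c(q)}, the cluster is
#' \eqn{C = \{q \ne anchor : |c(q) - c(anchor)| \le windowNt/2,\
#' match(q) \ge t_{sub}\}} and
#' \deqn{WR = match(anchor) \times (1 + \min(1, \sum_{q \in C} match(q)/N)),}
#' with \eqn{N = windowNt - k + 1} the number of windows that fit in the
#' clustering window. An isolated anchor keeps its match score; a fully
#' packed window at most doubles it.
#'
#' @param anchorOffset 0-based offset of the anchor (must be present in
#'   \code{positions}).
#' @param positions data.frame from [scanSequence()] for the same sequence.
#' @param tSuboptimal Suboptimal match-score threshold.
#' @param windowNt Clustering window width in nt.
#' @return WR score, in \code{[match(anchor), 2 * match(anchor)]}.
#' @export
wrScore <- function(anchorOffset, positions, tSuboptimal, windowNt = 50L) {
  i <- match(anchorOffset, positions$offset)
  if (is.na(i))
    stop(sprintf("anchor offset %d not among scored positions", anchorOffset))
  k <- nchar(positions$kmer[1])
  .wrScores(positions$offset, positions$matchScore, i, tSuboptimal,
            windowNt, k)
}

#' Z-score and one-tailed normal p-value of a WR score
#'
#' \eqn{z = (WR - \mu)/\sigma} against the region-specific background WR
#' mean and sd, with the upper-tail normal p-value
#' \eqn{p = 1 - \Phi(z)}: the probability of a background WR score this far
#' above the mean.
#'
#' @param wr WR score(s).
#' @param bg A [BackgroundModel-class] (its \code{wrMean}/\code{wrSd} are
#'   used).
#' @return data.frame with columns \code{z} and \code{p}.
#' @export
zAndP <- function(wr, bg) {
  z <- (wr - wrMean(bg)) / wrSd(bg)
  data.frame(z = z, p = pnorm(z, lower.tail = FALSE))
}

.emptySites <- function() {
  data.frame(seqId = character(), anchorOffset = integer(),
             motifId = character(), protein = character(),
             kmer = character(), matchScore = numeric(),
             wrScore = numeric(), z = numeric(), p = numeric(),
             wrCutoff = numeric(), regionClass = character(),
             chrom = character(), genomicStart = integer(),
             conservationPassed = logical(), stringsAsFactors = FALSE)
}

# Collapse called anchors of the same motif closer than k nt, keeping the
# higher WR. sites sorted by anchorOffset.
.dedupSites <- function(sites, k) {
  n <- nrow(sites)
  if (n <= 1L) return(sites)
  keep <- integer(0)
  cur <- 1L
  for (i in 2:n) {
    if (sites$anchorOffset[i] - sites$anchorOffset[cur] < k) {
      if (sites$wrScore[i] > sites$wrScore[cur]) cur <- i
    } else {
      keep <- c(keep, cur)
      cur <- i
    }
  }
  sites[c(keep, cur), , drop = FALSE]
}

#' Call binding sites on one sequence
#'
#' Runs the full per-sequence pipeline for one motif: overlapping-window
#' scan, anchor selection against the significant threshold, WR scoring
#' with suboptimal neighbors, and the final significance rule.
#'
#' In \code{database-genome} mode, anchor and suboptimal thresholds come
#' from the region-matched empirical background (match-score sample), the
#' WR score is converted to a Z-score against that region's background WR
#' mean/sd, and only sites with one-tailed normal \code{p < finalP}
#' (default 0.05) are reported. In \code{other-genome} mode, thresholds are
#' the motif's theoretical (analytic-distribution) cutoffs, and a site is
#' kept when its WR score reaches the WR of a bare anchor at the
#' significant threshold (reported as \code{wrCutoff}); no z/p is computed.
#'
#' Overlapping calls of the same motif closer than k nt are collapsed to
#' the highest-WR anchor.
#'
#' @param seq RNA string.
#' @param m A [Motif-class].
#' @param stringency A [StringencyLevel-class] or tier name.
#' @param mode \code{"database-genome"} or \code{"other-genome"}.
#' @param backgrounds A [BackgroundModel-class], or a list of them named by
#'   region class (database-genome mode).
#' @param regionClassifier \code{NULL} (all positions get the single
#'   background's class, or \code{defaultClass}), a single class name, or a
#'   function mapping a vector of 0-based anchor offsets to class names.
#' @param defaultClass Region class used when no classifier or single-class
#'   background applies.
#' @param baseFreqs Base frequencies for the theoretical threshold
#'   (other-genome mode).
#' @param windowNt WR window width (nt).
#' @param finalP Final acceptance p-value (database-genome mode).
#' @param seqId Identifier recorded in the result.
#' @return data.frame of binding sites (one row per called anchor) with
#'   columns seqId, anchorOffset, motifId, protein, kmer, matchScore,
#'   wrScore, z, p, wrCutoff, regionClass, chrom, genomicStart,
#'   conservationPassed; attributes \code{nWindows} and \code{nAnchors}
#'   carry scan accounting.
#' @export
callSites <- function(seq, m, stringency = stringencyLevel("medium"),
                      mode = c("database-genome", "other-genome"),
                      backgrounds = NULL, regionClassifier = NULL,
                      defaultClass = "mid_intron_intergenic",
                      baseFreqs = rep(0.25, 4), windowNt = 50L,
                      finalP = 0.05, seqId = "seq1") {
  mode <- match.arg(mode)
  if (is.character(stringency)) stringency <- stringencyLevel(stringency)
  k <- motifLength(m)
  pos <- scanSequence(m, seq, seqId = seqId)
  out <- .emptySites()
  attr(out, "nWindows") <- nrow(pos)
  attr(out, "nAnchors") <- 0L
  if (!nrow(pos)) return(out)

  if (mode == "database-genome") {
    if (is(backgrounds, "BackgroundModel"))
      backgrounds <- setNames(list(backgrounds), backgrounds@regionClass)
    if (is.null(backgrounds) || !length(backgrounds))
      stop("database-genome mode requires background models")
    classes <- if (is.function(regionClassifier)) {
      regionClassifier(pos$offset)
    } else if (is.character(regionClassifier)) {
      rep(regionClassifier[1], nrow(pos))
    } else if (length(backgrounds) == 1L) {
      rep(names(backgrounds), nrow(pos))
    } else rep(defaultClass, nrow(pos))
    missing <- setdiff(unique(classes), names(backgrounds))
    if (length(missing))
      stop(sprintf("no background model for region class(es): %s",
                   paste(missing, collapse = ", ")))
    rows <- list()
    nAnchors <- 0L
    for (cl in unique(classes)) {
      bg <- backgrounds[[cl]]
      tSig <- .thresholdFor(bg@matchScores, pSignificant(stringency))
      tSub <- .thresholdFor(bg@matchScores, pSuboptimal(stringency))
      anchorIdx <- which(classes == cl & pos$matchScore >= tSig)
      nAnchors <- nAnchors + length(anchorIdx)
      if (!length(anchorIdx)) next
      wr <- .wrScores(pos$offset, pos$matchScore, anchorIdx, tSub,
                      windowNt, k)
      zp <- zAndP(wr, bg)
      ok <- zp$p < finalP
      if (!any(ok)) next
      idx <- anchorIdx[ok]
      rows[[cl]] <- data.frame(
        seqId = pos$seqId[idx], anchorOffset = pos$offset[idx],
        motifId = motifId(m), protein = motifProtein(m),
        kmer = pos$kmer[idx], matchScore = pos$matchScore[idx],
        wrScore = wr[ok], z = zp$z[ok], p = zp$p[ok],
        wrCutoff = NA_real_, regionClass = cl,
        chrom = NA_character_, genomicStart = NA_integer_,
        conservationPassed = NA, stringsAsFactors = FALSE)
    }
    sites <- if (length(rows)) do.call(rbind, rows) else .emptySites()
  } else {
    th <- theoreticalThreshold(m, stringency, baseFreqs)
    anchorIdx <- which(pos$matchScore >= th["significant"])
    nAnchors <- length(anchorIdx)
    if (length(anchorIdx)) {
      wr <- .wrScores(pos$offset, pos$matchScore, anchorIdx,
                      th["suboptimal"], windowNt, k)
      cutoff <- th[["significant"]]  # WR of a bare anchor at t_significant
      ok <- wr >= cutoff
      idx <- anchorIdx[ok]
      sites <- data.frame(
        seqId = pos$seqId[idx], anchorOffset = pos$offset[idx],
        motifId = motifId(m), protein = motifProtein(m),
        kmer = pos$kmer[idx], matchScore = pos$matchScore[idx],
        wrScore = wr[ok], z = NA_real_, p = NA_real_,
        wrCutoff = cutoff, regionClass = NA_character_,
        chrom = NA_character_, genomicStart = NA_integer_,
        conservationPassed = NA, stringsAsFactors = FALSE)
    } else sites <- .emptySites()
  }
  sites <- sites[order(sites$anchorOffset), , drop = FALSE]
  sites <- .dedupSites(sites, k)
  rownames(sites) <- NULL
  attr(sites, "nWindows") <- nrow(pos)
  attr(sites, "nAnchors") <- nAnchors
  sites
}
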