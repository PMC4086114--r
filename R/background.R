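# Empirical background calibration: p-values, thresholds, and model building.

# sortedScores ascending; vectorized over score.
.empiricalP <- function(sortedScores, score) {
  n <- length(sortedScores)
  nBelow <- findInterval(score, sortedScores, left.open = TRUE)  # #{bg < s}
  (1 + (n - nBelow)) / (1 + n)
}

#' Empirical match-score p-value
#'
#' The probability that a background match score is at least as high as the
#' observed score, with the finite-sample correction
#' \eqn{p = (1 + \#\{bg \ge s\}) / (1 + n)} so that p is never 0. Monotone
#' non-increasing in the score.
#'
#' @param bg A [BackgroundModel-class], or a sorted numeric sample of
#'   background match scores.
#' @param score Observed match score(s).
#' @return p-value(s) in (0, 1].
#' @export
setGeneric("empiricalPvalue", function(bg, score)
  standardGeneric("empiricalPvalue"))

#' @rdname empiricalPvalue
setMethod("empiricalPvalue", "BackgroundModel", function(bg, score) {
  .empiricalP(bg@matchScores, score)
})

#' @rdname empiricalPvalue
setMethod("empiricalPvalue", "numeric", function(bg, score) {
  if (is.unsorted(bg)) bg <- sort(bg)
  .empiricalP(bg, score)
})

.thresholdFor <- function(sortedScores, p) {
  stopifnot(p > 0, p < 1)
  u <- unique(sortedScores)
  pv <- .empiricalP(sortedScores, u)
  ok <- which(pv < p)
  if (!length(ok)) {
    warning(sprintf("no score reaches p < %g on this background (n = %d)",
                    p, length(sortedScores)))
    return(Inf)
  }
  u[ok[1]]
}

#' Score threshold for an empirical p-value
#'
#' The smallest background score t with \code{empiricalPvalue(bg, t) < p};
#' sites scoring at least t are called at that p-value level. Returns
#' \code{Inf} (with a warning) when no score qualifies, i.e. p is below the
#' resolution \code{1/(1 + n)} of the sample.
#'
#' @param bg A [BackgroundModel-class] or sorted numeric background sample.
#' @param p Target p-value in (0, 1).
#' @return Score threshold (possibly \code{Inf}).
#' @export
setGeneric("thresholdFor", function(bg, p) standardGeneric("thresholdFor"))

#' @rdname thresholdFor
setMethod("thresholdFor", "BackgroundModel", function(bg, p) {
  .thresholdFor(bg@matchScores, p)
})

#' @rdname thresholdFor
setMethod("thresholdFor", "numeric", function(bg, p) {
  if (is.unsorted(bg)) bg <- sort(bg)
  .thresholdFor(bg, p)
})

#' Build a per-motif, per-region background model
#'
#' Scans the supplied background sequences of one genomic region class with
#' the motif, collects all valid-window match scores (the empirical match
#' background), then runs the full anchor-and-WR procedure on those same
#' sequences at the given stringency to obtain the background WR-score
#' sample, whose mean and sd feed the Z-score of candidate sites.
#'
#' @param m A [Motif-class].
#' @param sequences Character vector of background RNA sequences.
#' @param regionClass One of [regionClasses()].
#' @param stringency A [StringencyLevel-class] or tier name.
#' @param windowNt WR clustering window width in nt.
#' @return A [BackgroundModel-class].
#' @details Errors if fewer than 1000 scannable windows or fewer than 200
#'   background anchors are available (supply a larger background), or if
#'   the WR sample is degenerate (sd = 0, e.g. an all-uniform motif).
#' @export
buildBackground <- function(m, sequences, regionClass = "mid_intron_intergenic",
                            stringency = stringencyLevel("medium"),
                            windowNt = 50L) {
  if (is.character(stringency)) stringency <- stringencyLevel(stringency)
  regionClass <- match.arg(regionClass, regionClasses())
  k <- motifLength(m)
  L <- .logOdds(m)
  scans <- lapply(sequences, function(s) .scanCodes(.encodeRNA(s), L))
  all <- sort(unlist(lapply(scans, `[[`, "score"), use.names = FALSE))
  if (length(all) < 1000L)
    stop(sprintf(
      "insufficient background: %d scannable windows (< 1000); supply a larger background set",
      length(all)))
  tSig <- .thresholdFor(all, pSignificant(stringency))
  tSub <- .thresholdFor(all, pSuboptimal(stringency))
  wr <- unlist(lapply(scans, function(sc) {
    anchors <- which(sc$score >= tSig)
    if (!length(anchors)) return(numeric())
    .wrScores(sc$offset, sc$score, anchors, tSub, windowNt, k)
  }), use.names = FALSE)
  if (length(wr) < 200L)
    stop(sprintf(
      "insufficient background: %d background anchors (< 200); supply a larger background set",
      length(wr)))
  s <- stats::sd(wr)
  if (!(s > 0))
    stop("degenerate background: WR scores have zero variance")
  BackgroundModel(motifId(m), regionClass, all, mean(wr), s, length(wr))
}

#' Serialize a background model to a TSV + JSON bundle
#'
#' Writes \code{<prefix>.scores.tsv} (the sorted match-score sample) and
#' \code{<prefix>.json} (motif id, region class, n, WR mean/sd, seed).
#'
#' @param bg A [BackgroundModel-class].
#' @param prefix Output path prefix.
#' @param seed Optional RNG seed recorded in the metadata.
#' @return Invisibly, the two file paths.
#' @export
writeBackground <- function(bg, prefix, seed = NA_integer_) {
  scoresPath <- paste0(prefix, ".scores.tsv")
  metaPath <- paste0(prefix, ".json")
  write.table(data.frame(match_score = bg@matchScores), scoresPath,
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    motif_id = bg@motifId, region_class = bg@regionClass,
    n_match = nMatch(bg), wr_mean = bg@wrMean, wr_sd = bg@wrSd,
    n_wr = bg@nWr, seed = seed), metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(scoresPath, metaPath))
}

#' Read a background model from a TSV + JSON bundle
#'
#' @param prefix Path prefix used by [writeBackground()].
#' @return A [BackgroundModel-class].
#' @export
readBackground <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  scores <- read.table(paste0(prefix, ".scores.tsv"), header = TRUE,
                       sep = "\t")$match_score
  BackgroundModel(meta$motif_id, meta$region_class, scores,
                  meta$wr_mean, meta$wr_sd, meta$n_wr)
}
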