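# CLIP-style validation protocol: strong/weak enrichment testing.

.hitIds <- function(x) {
  if (is.data.frame(x)) unique(x$seqId) else unique(as.character(x))
}

#' Tabulate motif detection in strong vs weak binder sets
#'
#' A sequence counts as "detected" once, regardless of how many sites it
#' carries. The rosters must be disjoint.
#'
#' @param strongSites,weakSites Binding-site data.frames (with a
#'   \code{seqId} column) or character vectors of sequence ids carrying at
#'   least one site.
#' @param strongIds,weakIds Full id rosters of the two sets.
#' @return A [ContingencyTable-class].
#' @export
tabulateHits <- function(strongSites, weakSites, strongIds, weakIds) {
  if (length(intersect(strongIds, weakIds)))
    stop("strong and weak rosters overlap")
  sHit <- .hitIds(strongSites)
  wHit <- .hitIds(weakSites)
  if (!all(sHit %in% strongIds) || !all(wHit %in% weakIds))
    stop("site seq ids must belong to their set's roster")
  a <- length(sHit)
  c_ <- length(wHit)
  ContingencyTable(a, length(strongIds) - a, c_, length(weakIds) - c_)
}

#' One-tailed Fisher's exact test for enrichment in the strong set
#'
#' Upper-tail hypergeometric probability \eqn{P(X \ge a)} of observing at
#' least \code{a} detected strong sequences given the table margins, i.e.
#' enrichment of detected motifs among strong binders relative to weak
#' binders.
#'
#' @param t A [ContingencyTable-class].
#' @param log10 Return log10(p) instead of p (for values that underflow).
#' @return The one-tailed p-value (or its log10).
#' @export
fisherOneTailed <- function(t, log10 = FALSE) {
  lp <- stats::phyper(t@a - 1L, t@a + t@b, t@c + t@d, t@a + t@c,
                      lower.tail = FALSE, log.p = TRUE)
  if (log10) lp / log(10) else exp(lp)
}

#' Sensitivity and specificity of a detection table
#'
#' Sensitivity \code{a/(a+b)} (detected fraction of strong binders) and
#' specificity \code{d/(c+d)} (undetected fraction of weak binders);
#' \code{NA} with a warning when a margin is empty.
#'
#' @param t A [ContingencyTable-class].
#' @return Named numeric: \code{sensitivity}, \code{specificity}.
#' @export
sensitivitySpecificity <- function(t) {
  sens <- if (t@a + t@b > 0L) t@a / (t@a + t@b) else NA_real_
  spec <- if (t@c + t@d > 0L) t@d / (t@c + t@d) else NA_real_
  if (is.na(sens) || is.na(spec))
    warning("undefined sensitivity/specificity: empty margin")
  c(sensitivity = sens, specificity = spec)
}

# Fast per-record detection. level: "match" (any anchor-passing window),
# "wr" (full WR + final p rule), "wr_conservation" (plus the filter).
.detectHits <- function(records, m, bgs, stringency, level = "wr",
                        annotation = NULL, track = NULL,
                        reference = NULL, windowNt = 50L, finalP = 0.05,
                        environmentNt = 50L, flankNt = 100L) {
  if (is(bgs, "BackgroundModel"))
    bgs <- setNames(list(bgs), bgs@regionClass)
  if (is.character(stringency)) stringency <- stringencyLevel(stringency)
  k <- motifLength(m)
  L <- .logOdds(m)
  tSig <- vapply(bgs, function(b)
    .thresholdFor(b@matchScores, pSignificant(stringency)), numeric(1L))
  tSub <- vapply(bgs, function(b)
    .thresholdFor(b@matchScores, pSuboptimal(stringency)), numeric(1L))
  mu <- vapply(bgs, wrMean, numeric(1L))
  sd_ <- vapply(bgs, wrSd, numeric(1L))
  single <- length(bgs) == 1L
  if (level == "wr_conservation" && is.null(reference)) {
    if (is.null(track) || is.null(annotation))
      stop("conservation level requires a track and an annotation")
    reference <- intronicReferenceMean(track, annotation, flankNt)
  }
  out <- logical(nrow(records))
  for (ri in seq_len(nrow(records))) {
    rec <- records[ri, ]
    sc <- .scanCodes(.encodeRNA(rec$sequence), L)
    if (!length(sc$offset)) next
    cls <- if (single) rep(names(bgs), length(sc$offset))
    else if (!is.null(annotation) && !is.na(rec$chrom)) {
      gs <- .genomicStart(rec, sc$offset, k)
      classifyRegion(annotation,
        GenomicRanges::GRanges(rec$chrom, IRanges::IRanges(gs, gs + k - 1L)),
        flankNt)
    } else rep("mid_intron_intergenic", length(sc$offset))
    anchorIdx <- which(sc$score >= tSig[cls])
    if (!length(anchorIdx)) next
    if (level == "match") {
      out[ri] <- TRUE
      next
    }
    hit <- FALSE
    for (cl in unique(cls[anchorIdx])) {
      ai <- anchorIdx[cls[anchorIdx] == cl]
      wr <- .wrScores(sc$offset, sc$score, ai, tSub[[cl]], windowNt, k)
      p <- pnorm((wr - mu[[cl]]) / sd_[[cl]], lower.tail = FALSE)
      ok <- which(p < finalP)
      if (!length(ok)) next
      if (level == "wr") {
        hit <- TRUE
        break
      }
      # conservation: mid-intron/intergenic sites must reach the reference
      for (j in ok) {
        if (cl != "mid_intron_intergenic" || is.na(rec$chrom)) {
          hit <- TRUE
          break
        }
        gs <- .genomicStart(rec, sc$offset[ai[j]], k)
        mc <- meanConservation(track, rec$chrom, gs, gs + k - 1L,
                               environmentNt)
        if (is.na(mc) || mc >= reference) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    out[ri] <- hit
  }
  out
}

#' Which sequences carry at least one predicted binding site
#'
#' Batched per-sequence detection used by the enrichment protocol, at one
#' of three evidence levels: raw match score only, the full WR + Z-score
#' rule, or WR with the conservation filter.
#'
#' @param records Query-record data.frame.
#' @param m A [Motif-class].
#' @param backgrounds A [BackgroundModel-class] or class-named list.
#' @param stringency Tier name or [StringencyLevel-class].
#' @param level \code{"wr"}, \code{"match"}, or \code{"wr_conservation"}.
#' @param annotation,track Needed for multi-class records and the
#'   conservation level.
#' @param windowNt,finalP,environmentNt,flankNt Pipeline tunables.
#' @return Logical vector, one element per record.
#' @export
detectBoundSequences <- function(records, m, backgrounds,
                                 stringency = "medium",
                                 level = c("wr", "match",
                                           "wr_conservation"),
                                 annotation = NULL, track = NULL,
                                 windowNt = 50L, finalP = 0.05,
                                 environmentNt = 50L, flankNt = 100L) {
  level <- match.arg(level)
  .detectHits(records, m, backgrounds, stringency, level, annotation,
              track, NULL, windowNt, finalP, environmentNt, flankNt)
}

#' Ablation comparison of the prediction rules
#'
#' Runs the enrichment protocol on identical strong/weak inputs under
#' three configurations -- match score only, WR without conservation, and
#' WR with conservation filtering (when a track and annotation are
#' supplied) -- and reports the contingency table, one-tailed Fisher p and
#' sensitivity/specificity side by side.
#'
#' @param strong,weak Query-record data.frames.
#' @param m A [Motif-class].
#' @param backgrounds A [BackgroundModel-class] or class-named list.
#' @param stringency Tier name or [StringencyLevel-class].
#' @param annotation,track Toy gene model and conservation track; when
#'   either is NULL the conservation configuration is skipped.
#' @param windowNt,finalP,environmentNt,flankNt Pipeline tunables.
#' @return data.frame with one row per configuration: a, b, c, d,
#'   fisher_log10p, sensitivity, specificity.
#' @export
ablationCompare <- function(strong, weak, m, backgrounds,
                            stringency = "medium", annotation = NULL,
                            track = NULL, windowNt = 50L, finalP = 0.05,
                            environmentNt = 50L, flankNt = 100L) {
  configs <- c("match_only", "wr_no_conservation")
  levels <- c("match", "wr")
  if (!is.null(track) && !is.null(annotation)) {
    configs <- c(configs, "wr_with_conservation")
    levels <- c(levels, "wr_conservation")
  }
  rows <- lapply(seq_along(configs), function(i) {
    sHit <- .detectHits(strong, m, backgrounds, stringency, levels[i],
                        annotation, track, NULL, windowNt, finalP,
                        environmentNt, flankNt)
    wHit <- .detectHits(weak, m, backgrounds, stringency, levels[i],
                        annotation, track, NULL, windowNt, finalP,
                        environmentNt, flankNt)
    tab <- tabulateHits(strong$id[sHit], weak$id[wHit], strong$id,
                        weak$id)
    ss <- suppressWarnings(sensitivitySpecificity(tab))
    data.frame(config = configs[i], a = tab@a, b = tab@b, c = tab@c,
               d = tab@d, fisher_log10p = fisherOneTailed(tab, log10 = TRUE),
               sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
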