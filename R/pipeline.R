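# Pipeline orchestration: configuration, per-record execution, run report.

#' Pipeline run configuration
#'
#' Bundles all tunables of a run. In \code{database-genome} mode,
#' \code{backgrounds} must provide, per motif id, a
#' [BackgroundModel-class] or a list of them named by region class;
#' \code{annotation} (a [RegionAnnotation-class]) enables per-site region
#' classification of coordinate-anchored records, and \code{track} (a
#' [ConservationTrack-class]) enables the conservation filter. FASTA
#' records without genomic anchors are classified as \code{defaultClass}.
#'
#' @param stringency Tier name or [StringencyLevel-class]; default medium.
#' @param mode \code{"database-genome"} or \code{"other-genome"}.
#' @param backgrounds Named list: motif id -> BackgroundModel or
#'   class-named list of BackgroundModels.
#' @param annotation Optional [RegionAnnotation-class].
#' @param track Optional [ConservationTrack-class].
#' @param conservationEnabled Apply the conservation filter (default TRUE;
#'   ignored without \code{track} + \code{annotation}).
#' @param windowNt WR window width (nt).
#' @param finalP Final site acceptance p-value.
#' @param baseFreqs Base frequencies for other-genome thresholds.
#' @param flankNt Splice-flank width (nt).
#' @param environmentNt Conservation environment width (nt).
#' @param defaultClass Region class for unanchored records.
#' @param seed RNG seed recorded in the run report.
#' @return A validated configuration list of class \code{"RunConfig"}.
#' @export
runConfig <- function(stringency = "medium",
                      mode = c("database-genome", "other-genome"),
                      backgrounds = NULL, annotation = NULL, track = NULL,
                      conservationEnabled = TRUE, windowNt = 50L,
                      finalP = 0.05, baseFreqs = rep(0.25, 4),
                      flankNt = 100L, environmentNt = 50L,
                      defaultClass = "mid_intron_intergenic",
                      seed = NA_integer_) {
  mode <- match.arg(mode)
  if (is.character(stringency)) stringency <- stringencyLevel(stringency)
  stopifnot(finalP > 0, finalP < 1, windowNt > 0)
  cfg <- list(stringency = stringency, mode = mode,
              backgrounds = backgrounds, annotation = annotation,
              track = track, conservationEnabled = conservationEnabled,
              windowNt = as.integer(windowNt), finalP = finalP,
              baseFreqs = baseFreqs, flankNt = as.integer(flankNt),
              environmentNt = as.integer(environmentNt),
              defaultClass = defaultClass, seed = seed)
  class(cfg) <- "RunConfig"
  cfg
}

.motifBackgrounds <- function(config, m) {
  bgs <- config$backgrounds[[motifId(m)]]
  if (is(bgs, "BackgroundModel"))
    bgs <- setNames(list(bgs), bgs@regionClass)
  bgs
}

# Genomic start (1-based, 5'-most base on the + reference) of a site at
# 0-based offset in a record.
.genomicStart <- function(rec, offset, k) {
  if (is.na(rec$gstart)) return(rep(NA_integer_, length(offset)))
  if (identical(rec$strand, "-")) rec$gend - offset - k + 1L
  else rec$gstart + offset
}

#' Run the full prediction pipeline over a batch of records
#'
#' For every record x motif pair: scan, anchor selection, WR scoring,
#' Z-score significance (database-genome mode) or theoretical-threshold
#' acceptance (other-genome mode), region classification of each site, and
#' finally the conservation filter over mid-intron/intergenic sites when a
#' track and annotation are configured.
#'
#' @param records Query-record data.frame from [readQueryFasta()] or
#'   [readCoordinates()].
#' @param motifs A [Motif-class] or list of them.
#' @param config A configuration from [runConfig()].
#' @return List with \code{sites} (binding-site data.frame over the whole
#'   batch) and \code{report} (record/window/anchor/site counts, rejection
#'   table, seed).
#' @export
runPipeline <- function(records, motifs, config = runConfig()) {
  if (is(motifs, "Motif")) motifs <- list(motifs)
  if (!length(motifs)) stop("no motifs selected")
  if (!nrow(records)) stop("no query records")
  db <- config$mode == "database-genome"
  if (db && is.null(config$backgrounds))
    stop("database-genome mode requires background models")
  nWindows <- 0L
  nAnchors <- 0L
  out <- list()
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    k <- motifLength(m)
    bgs <- if (db) .motifBackgrounds(config, m) else NULL
    if (db && is.null(bgs))
      stop(sprintf("no background models for motif '%s'", motifId(m)))
    for (ri in seq_len(nrow(records))) {
      rec <- records[ri, ]
      classifier <- if (db && !is.null(config$annotation) &&
                        !is.na(rec$chrom)) {
        function(offsets) {
          gs <- .genomicStart(rec, offsets, k)
          gr <- GenomicRanges::GRanges(rec$chrom,
                  IRanges::IRanges(gs, gs + k - 1L))
          classifyRegion(config$annotation, gr, config$flankNt)
        }
      } else if (db) config$defaultClass else NULL
      sites <- callSites(rec$sequence, m, stringency = config$stringency,
                         mode = config$mode, backgrounds = bgs,
                         regionClassifier = classifier,
                         defaultClass = config$defaultClass,
                         baseFreqs = config$baseFreqs,
                         windowNt = config$windowNt,
                         finalP = config$finalP, seqId = rec$id)
      nWindows <- nWindows + attr(sites, "nWindows")
      nAnchors <- nAnchors + attr(sites, "nAnchors")
      if (nrow(sites)) {
        sites$chrom <- rec$chrom
        sites$genomicStart <- .genomicStart(rec, sites$anchorOffset, k)
        out[[length(out) + 1L]] <- sites
      }
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else .emptySites()
  nBefore <- nrow(sites)
  if (db && config$conservationEnabled && !is.null(config$track) &&
      !is.null(config$annotation) && nrow(sites)) {
    reference <- intronicReferenceMean(config$track, config$annotation,
                                       config$flankNt)
    sites <- conservationFilter(sites, config$track, reference,
                                enabled = TRUE,
                                environmentNt = config$environmentNt)
  }
  sites <- sites[order(sites$protein, sites$motifId, sites$seqId,
                       sites$anchorOffset), , drop = FALSE]
  rownames(sites) <- NULL
  rej <- attr(records, "rejections")
  if (is.null(rej)) rej <- .rejection(character(), character())
  report <- list(
    nRecords = nrow(records), nMotifs = length(motifs),
    nRejected = nrow(rej), rejections = rej,
    nWindows = nWindows, nAnchors = nAnchors,
    nSitesBeforeConservation = nBefore, nSites = nrow(sites),
    mode = config$mode, stringency = config$stringency@name,
    seed = config$seed)
  list(sites = sites, report = report)
}

#' Write the run report as JSON
#'
#' @param report Report list from [runPipeline()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
writeRunReport <- function(report, file) {
  jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
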