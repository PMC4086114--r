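# Input readers and output writers.
#
# Query records are plain data.frames with columns id, sequence (RNA,
# T projected to U), chrom, gstart, gend (1-based inclusive genomic anchor,
# NA for plain FASTA), strand, source; rejected entries are reported in the
# "rejections" attribute (id, reason) rather than aborting the batch.

MIN_QUERY_NT <- 21L
MAX_QUERY_NT <- 10000L
MAX_BATCH <- 5000L

.emptyRecords <- function() {
  data.frame(id = character(), sequence = character(),
             chrom = character(), gstart = integer(), gend = integer(),
             strand = character(), source = character(),
             stringsAsFactors = FALSE)
}

.rejection <- function(id, reason) {
  data.frame(id = id, reason = reason, stringsAsFactors = FALSE)
}

# Validate lengths and batch size; returns records + rejections attr.
.validateRecords <- function(rec, rej) {
  n <- nchar(rec$sequence)
  tooShort <- n < MIN_QUERY_NT
  tooLong <- n > MAX_QUERY_NT
  if (any(tooShort))
    rej <- rbind(rej, .rejection(rec$id[tooShort], "length_below_minimum"))
  if (any(tooLong))
    rej <- rbind(rej, .rejection(rec$id[tooLong], "length_above_maximum"))
  rec <- rec[!tooShort & !tooLong, , drop = FALSE]
  if (nrow(rec) > MAX_BATCH) {
    rej <- rbind(rej, .rejection(rec$id[(MAX_BATCH + 1L):nrow(rec)],
                                 "batch_limit_exceeded"))
    rec <- rec[seq_len(MAX_BATCH), , drop = FALSE]
  }
  if (!nrow(rec))
    stop("no valid query records after validation")
  rownames(rec) <- NULL
  attr(rec, "rejections") <- rej
  rec
}

.dedupIds <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  warning("duplicate record ids disambiguated with numeric suffixes")
  make.unique(ids, sep = "_dup")
}

#' Read query sequences from a FASTA file
#'
#' Sequences are projected to the RNA alphabet (T to U, uppercased).
#' Records shorter than 21 nt or longer than 10,000 nt are rejected with a
#' reason; batches are capped at 5,000 records (the excess is rejected).
#' Rejections are recorded in the \code{"rejections"} attribute of the
#' result and the run continues on the valid records; an empty valid set
#' is an error. Duplicate ids are disambiguated with suffixes.
#'
#' @param file FASTA path.
#' @return Query-record data.frame (see package overview), with a
#'   \code{"rejections"} attribute.
#' @export
readQueryFasta <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  ids <- .dedupIds(sub("\\s.*$", "", names(ss)))
  rec <- data.frame(
    id = ids,
    sequence = chartr("Tt", "Uu", toupper(as.character(ss))),
    chrom = NA_character_, gstart = NA_integer_, gend = NA_integer_,
    strand = NA_character_, source = "fasta", stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  .validateRecords(rec, .rejection(character(), character()))
}

#' Read query records from BED-style genomic coordinates
#'
#' Lines are \code{chrom start end [name [score [strand]]]} (0-based
#' half-open, as in BED). Sequences are extracted from the supplied
#' reference; minus-strand records are reverse-complemented to the sense
#' strand before scanning, and the genomic anchor is retained so output
#' coordinates can be reported. Malformed lines, intervals outside the
#' reference, and length violations are rejected with reasons.
#'
#' @param file BED path or character vector of lines.
#' @param reference Reference sequences: FASTA path or a named character
#'   vector / \code{DNAStringSet} of chromosome sequences.
#' @return Query-record data.frame with a \code{"rejections"} attribute.
#' @export
readCoordinates <- function(file, reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- Biostrings::readBStringSet(reference)
  if (is(reference, "XStringSet"))
    reference <- setNames(as.character(reference),
                          sub("\\s.*$", "", names(reference)))
  reference <- toupper(reference)
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file)
           else as.character(file)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  rej <- .rejection(character(), character())
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    lineId <- sprintf("line_%d", i)
    if (length(f) < 3L) {
      rej <- rbind(rej, .rejection(lineId, "malformed_line"))
      next
    }
    chrom <- f[1]
    name <- if (length(f) >= 4L && nzchar(f[4]) && f[4] != ".") f[4]
            else lineId
    start0 <- suppressWarnings(as.integer(f[2]))
    end0 <- suppressWarnings(as.integer(f[3]))
    if (is.na(start0) || is.na(end0) || end0 <= start0) {
      rej <- rbind(rej, .rejection(name, "malformed_line"))
      next
    }
    if (name == lineId) name <- sprintf("%s:%d-%d", chrom, start0, end0)
    strand <- if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "+"
    if (!chrom %in% names(reference) ||
        end0 > nchar(reference[[chrom]]) || start0 < 0L) {
      rej <- rbind(rej, .rejection(name, "outside_reference"))
      next
    }
    s <- substr(reference[[chrom]], start0 + 1L, end0)
    if (strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        chartr("Uu", "Tt", s))))
    rows[[length(rows) + 1L]] <- data.frame(
      id = name, sequence = chartr("Tt", "Uu", s), chrom = chrom,
      gstart = start0 + 1L, gend = end0, strand = strand,
      source = "coordinates", stringsAsFactors = FALSE)
  }
  rec <- if (length(rows)) do.call(rbind, rows) else .emptyRecords()
  rec$id <- .dedupIds(rec$id)
  .validateRecords(rec, rej)
}

.fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

#' Write the binding-site summary table
#'
#' A TSV with one row per predicted site: seq_id, position_in_sequence
#' (1-based offset of the site in the query), genomic_coordinate
#' (\code{chrom:pos}, 1-based, or NA), protein, motif, the matching k-mer,
#' match_score, wr_score, and the statistical measures: z and p in
#' database-genome mode, or the theoretical WR cutoff in other-genome mode.
#' Rows are grouped by protein so all motifs ascribed to one protein are
#' listed together.
#'
#' @param sites Binding-site data.frame.
#' @param file Output path or connection.
#' @param mode Pipeline mode the sites came from.
#' @return Invisibly, the lines written.
#' @export
writeSummary <- function(sites, file,
                         mode = c("database-genome", "other-genome")) {
  mode <- match.arg(mode)
  statCols <- if (mode == "database-genome") c("z", "p") else "wr_cutoff"
  header <- paste(c("seq_id", "position_in_sequence", "genomic_coordinate",
                    "protein", "motif", "kmer", "match_score", "wr_score",
                    statCols), collapse = "\t")
  if (nrow(sites)) {
    o <- order(sites$protein, sites$motifId, sites$seqId,
               sites$anchorOffset)
    s <- sites[o, , drop = FALSE]
    coord <- ifelse(is.na(s$chrom) | is.na(s$genomicStart), "NA",
                    sprintf("%s:%d", s$chrom, s$genomicStart))
    stat <- if (mode == "database-genome")
      paste(.fmtNum(s$z), .fmtNum(s$p), sep = "\t")
    else .fmtNum(s$wrCutoff)
    body <- paste(s$seqId, s$anchorOffset + 1L, coord, s$protein,
                  s$motifId, s$kmer, .fmtNum(s$matchScore),
                  .fmtNum(s$wrScore), stat, sep = "\t")
  } else body <- character()
  lines <- c(header, body)
  writeLines(lines, file)
  invisible(lines)
}

#' Write predicted sites as a BedGraph track file
#'
#' One track block per protein; one line per site at its first (5'-most on
#' the plus-strand reference) genomic position: \code{chrom start0
#' start0+1 wr_score} with 0-based half-open coordinates. Sites without
#' genomic anchors are omitted with a warning.
#'
#' @param sites Binding-site data.frame.
#' @param file Output path or connection.
#' @return Invisibly, the lines written.
#' @export
writeBedGraph <- function(sites, file) {
  anchored <- sites[!is.na(sites$chrom) & !is.na(sites$genomicStart), ,
                    drop = FALSE]
  if (nrow(anchored) < nrow(sites))
    warning(sprintf("%d site(s) without genomic anchors omitted from BedGraph",
                    nrow(sites) - nrow(anchored)))
  lines <- character()
  for (prot in unique(anchored$protein[order(anchored$protein)])) {
    s <- anchored[anchored$protein == prot, , drop = FALSE]
    s <- s[order(s$chrom, s$genomicStart), , drop = FALSE]
    lines <- c(lines,
      sprintf("track type=bedGraph name=\"%s binding sites\"", prot),
      sprintf("%s\t%d\t%d\t%s", s$chrom, s$genomicStart - 1L,
              s$genomicStart, .fmtNum(s$wrScore)))
  }
  if (!nrow(anchored) && !length(lines))
    lines <- "track type=bedGraph name=\"binding sites\""
  writeLines(lines, file)
  invisible(lines)
}
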