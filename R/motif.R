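IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Parse an IUPAC consensus string into a Motif
#'
#' Each IUPAC symbol allowing d bases becomes a column assigning 1/d to each
#' allowed base and 0 elsewhere (e.g. R = A/G gives 0.5/0/0.5/0 over
#' A,C,G,U); T is treated as U. Columns are then floored at 1e-3 and
#' renormalized for scoring, while the pre-flooring matrix is retained for
#' information content.
#'
#' @param text IUPAC consensus, 3--30 symbols, case-insensitive.
#' @param id Motif identifier.
#' @param protein Protein display name (defaults to \code{id}).
#' @return A [Motif-class] with \code{origin = "consensus"}.
#' @export
#' @examples
#' m <- parseIUPACConsensus("YCAY", "nova1", protein = "NOVA")
#' motifMatrix(m)
parseIUPACConsensus <- function(text, id, protein = id) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- strsplit(toupper(text), "")[[1]]
  bad <- !chars %in% names(IUPAC_MAP)
  if (any(bad))
    stop(sprintf("unknown IUPAC character '%s' at position %d",
                 chars[which(bad)[1]], which(bad)[1]))
  k <- length(chars)
  if (k < 3L || k > 30L)
    stop(sprintf("consensus length %d outside [3, 30]", k))
  m <- vapply(chars, function(ch) {
    allowed <- IUPAC_MAP[[ch]]
    col <- setNames(numeric(4L), RNA_BASES)
    col[allowed] <- 1 / length(allowed)
    col
  }, numeric(4L))
  Motif(id, m, protein = protein, origin = "consensus")
}

#' Read motifs from a MEME minimal-format file
#'
#' Accepts the minimal MEME motif format: a \code{MEME version} header, an
#' optional \code{ALPHABET=} line (ACGT or ACGU only), and one or more
#' \code{MOTIF} blocks each with a \code{letter-probability matrix:} line
#' followed by w rows of 4 probabilities. DNA-alphabet T columns are
#' relabeled U; matrix rows become motif columns in order.
#'
#' @param file Path to a MEME file, or a character vector of its lines.
#' @param protein Optional named character vector mapping motif ids to
#'   protein names; unmapped motifs use their id.
#' @return List of [Motif-class] objects in file order.
#' @export
readMEMEMotifs <- function(file, protein = NULL) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file)
           else as.character(file)
  lines <- trimws(lines)
  if (!any(grepl("^MEME version", lines)))
    stop("not a MEME motif file: missing 'MEME version' header")
  alpha <- grep("^ALPHABET\\s*=", lines, value = TRUE)
  if (length(alpha)) {
    ab <- toupper(gsub("^ALPHABET\\s*=\\s*", "", alpha[1]))
    if (!ab %in% c("ACGT", "ACGU"))
      stop(sprintf("unsupported alphabet '%s' (ACGT/ACGU only)", ab))
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts))
    stop("no MOTIF blocks found")
  motifs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    fields <- strsplit(lines[starts[i]], "\\s+")[[1]]
    id <- if (length(fields) >= 2L) fields[2] else sprintf("motif_%d", i)
    stop_i <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    block <- lines[starts[i]:stop_i]
    hdr <- grep("^letter-probability matrix", block)
    if (!length(hdr))
      stop(sprintf("motif '%s': missing letter-probability matrix", id))
    w <- suppressWarnings(as.integer(
      sub(".*\\bw\\s*=\\s*(\\d+).*", "\\1", block[hdr[1]])))
    rows <- block[-seq_len(hdr[1])]
    rows <- rows[nzchar(rows)]
    num <- grepl("^[-0-9.eE+ \t]+$", rows)
    rows <- rows[cumprod(num) == 1]  # stop at first non-numeric line
    if (!is.na(w)) {
      if (length(rows) < w)
        stop(sprintf("motif '%s': expected %d matrix rows, found %d",
                     id, w, length(rows)))
      rows <- rows[seq_len(w)]
    }
    vals <- lapply(strsplit(rows, "\\s+"), as.numeric)
    if (!length(vals) || any(lengths(vals) != 4L))
      stop(sprintf("motif '%s': matrix rows must have 4 probabilities", id))
    m <- do.call(cbind, vals)  # positions -> columns
    sums <- colSums(m)
    if (any(abs(sums - 1) > 1e-3))
      stop(sprintf("motif '%s': matrix row %d sums to %.4g, not 1",
                   id, which(abs(sums - 1) > 1e-3)[1],
                   sums[which(abs(sums - 1) > 1e-3)[1]]))
    m <- sweep(m, 2L, sums, "/")  # absorb <=1e-3 rounding
    prot <- if (!is.null(protein) && id %in% names(protein)) protein[[id]]
            else id
    motifs[[i]] <- Motif(id, m, protein = prot, origin = "pssm")
  }
  motifs
}

#' Write motifs to a MEME minimal-format file
#'
#' Serializes the pre-flooring probability matrices, so that a
#' read--write--read round trip reproduces each matrix exactly.
#'
#' @param motifs A [Motif-class] or list of them.
#' @param file Output path or connection.
#' @return Invisibly, the lines written.
#' @export
writeMEMEMotifs <- function(motifs, file) {
  if (is(motifs, "Motif")) motifs <- list(motifs)
  lines <- c("MEME version 4", "", "ALPHABET= ACGU", "")
  for (m in motifs) {
    mat <- motifRawMatrix(m)
    lines <- c(lines,
      sprintf("MOTIF %s %s", motifId(m), motifProtein(m)),
      sprintf("letter-probability matrix: alength= 4 w= %d", ncol(mat)),
      apply(mat, 2L, function(col)
        paste(sprintf("%.10g", col), collapse = " ")),
      "")
  }
  writeLines(lines, file)
  invisible(lines)
}

#' Load a batch of motifs from a TSV manifest
#'
#' The manifest has columns \code{id}, \code{protein}, \code{source}; a
#' source matching IUPAC symbols is parsed as a consensus, anything else is
#' taken as a path (relative to the manifest) to a MEME file whose motif of
#' that id is loaded.
#'
#' @param file Manifest path.
#' @return List of [Motif-class] objects.
#' @export
loadMotifManifest <- function(file) {
  tab <- read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("id", "protein", "source") %in% names(tab)))
  base <- dirname(file)
  lapply(seq_len(nrow(tab)), function(i) {
    src <- tab$source[i]
    if (grepl("^[ACGUTRYSWKMBDHVNacgutryswkmbdhvn]+$", src)) {
      parseIUPACConsensus(src, tab$id[i], protein = tab$protein[i])
    } else {
      path <- if (file.exists(src)) src else file.path(base, src)
      found <- readMEMEMotifs(path)
      hit <- Filter(function(m) motifId(m) == tab$id[i], found)
      if (!length(hit))
        stop(sprintf("motif '%s' not found in %s", tab$id[i], path))
      m <- hit[[1]]
      m@protein <- tab$protein[i]
      m
    }
  })
}

#' Information content of a motif, in bits
#'
#' Sum over columns of \eqn{2 + \sum_b p_b \log_2 p_b}, evaluated on the
#' pre-flooring matrix (so a uniform N column contributes exactly 0 and a
#' deterministic column exactly 2 bits). Serves as the length-and-complexity
#' summary underlying the theoretical threshold: longer and sharper motifs
#' carry more bits.
#'
#' @param m A [Motif-class].
#' @return Non-negative IC in bits, at most \code{2 * motifLength(m)}.
#' @export
#' @examples
#' informationContent(parseIUPACConsensus("ACGU", "m1"))  # 8 bits
#' informationContent(parseIUPACConsensus("NNNN", "m2"))  # 0 bits
informationContent <- function(m) {
  p <- motifRawMatrix(m)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  sum(2 + colSums(plogp))
}
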