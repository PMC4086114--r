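# Sequence encoding and motif scanning.
#
# All scanning is done on integer-encoded RNA (A=1, C=2, G=3, U=4, NA for
# any ambiguity code); windows containing ambiguous bases are skipped.

.encodeRNA <- function(seq) {
  chars <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  match(chars, RNA_BASES)
}

.logOdds <- function(m) log2(motifMatrix(m) / 0.25)

.scoreRange <- function(L) {
  c(min = sum(apply(L, 2L, min)), max = sum(apply(L, 2L, max)))
}

# Raw->normalized score for a vector of raw log-odds sums. Scores within
# 1e-9 of the endpoints are snapped so the best/worst k-mers score exactly
# 1/0 regardless of summation order.
.normalizeScore <- function(raw, rng) {
  if (rng["max"] - rng["min"] < 1e-12) return(rep(1, length(raw)))
  s <- as.numeric((raw - rng["min"]) / (rng["max"] - rng["min"]))
  s[abs(s - 1) < 1e-9] <- 1
  s[abs(s) < 1e-9] <- 0
  s
}

# Core windowed scorer on an integer-encoded sequence. Returns 0-based
# offsets and normalized scores of all unambiguous windows.
.scanCodes <- function(codes, L) {
  k <- ncol(L)
  n <- length(codes) - k + 1L
  if (n < 1L)
    return(list(offset = integer(), score = numeric()))
  raw <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) {
    cj <- codes[j:(j + n - 1L)]
    bad <- is.na(cj)
    if (any(bad)) {
      ok <- ok & !bad
      cj[bad] <- 1L
    }
    raw <- raw + L[cbind(cj, j)]
  }
  rng <- .scoreRange(L)
  list(offset = which(ok) - 1L, score = .normalizeScore(raw[ok], rng))
}

#' Match score of a k-mer against a motif
#'
#' The raw score is the log-odds sum \eqn{S = \sum_i \log_2(p_i(b_i)/0.25)}
#' over the floored motif matrix; the returned score is min--max normalized,
#' \eqn{(S - S_{min})/(S_{max} - S_{min})}, where \eqn{S_{max}} and
#' \eqn{S_{min}} are the best and worst achievable raw scores (column-wise
#' max/min). The column-wise argmax k-mer therefore scores exactly 1 and the
#' argmin k-mer exactly 0; a fully uniform motif (degenerate, S_max = S_min)
#' scores 1 for every k-mer.
#'
#' @param m A [Motif-class].
#' @param kmer RNA string of length \code{motifLength(m)} over A,C,G,U
#'   (T accepted and read as U). Ambiguity codes yield \code{NA}.
#' @return Score in [0, 1], or \code{NA} for an ambiguous k-mer.
#' @export
#' @examples
#' m <- parseIUPACConsensus("ACG", "m1")
#' matchScore(m, "ACG")   # 1
#' matchScore(m, "UUU")   # 0
matchScore <- function(m, kmer) {
  k <- motifLength(m)
  codes <- .encodeRNA(kmer)
  if (length(codes) != k)
    stop(sprintf("kmer length %d != motif length %d", length(codes), k))
  if (anyNA(codes)) return(NA_real_)
  L <- .logOdds(m)
  raw <- sum(L[cbind(codes, seq_len(k))])
  .normalizeScore(raw, .scoreRange(L))
}

#' Scan a sequence with a motif in overlapping windows
#'
#' Computes the match score for every window of the motif size along the
#' sequence (offsets 0 .. length - k), skipping windows that contain
#' ambiguous bases.
#'
#' @param m A [Motif-class].
#' @param seq RNA string (T read as U).
#' @param seqId Identifier recorded in the result.
#' @return data.frame with columns \code{seqId}, \code{offset} (0-based
#'   window start), \code{kmer}, \code{matchScore}; zero rows (with a
#'   warning) if the sequence is shorter than the motif.
#' @export
scanSequence <- function(m, seq, seqId = "seq1") {
  k <- motifLength(m)
  codes <- .encodeRNA(seq)
  if (length(codes) < k) {
    warning(sprintf("sequence '%s' shorter than motif (%d < %d): no windows",
                    seqId, length(codes), k))
    return(data.frame(seqId = character(), offset = integer(),
                      kmer = character(), matchScore = numeric()))
  }
  hits <- .scanCodes(codes, .logOdds(m))
  rna <- chartr("Tt", "Uu", toupper(seq))
  data.frame(
    seqId = rep(seqId, length(hits$offset)),
    offset = hits$offset,
    kmer = substring(rna, hits$offset + 1L, hits$offset + k),
    matchScore = hits$score,
    stringsAsFactors = FALSE)
}

#' Exact match-score distribution of a random k-mer
#'
#' Computes the distribution of the normalized match score for an iid
#' random k-mer with the given base frequencies, by per-column convolution
#' of the raw log-odds scores on a discretized grid (default bin 1e-4).
#' Because the distribution reflects both the motif length and its
#' column-entropy structure, it serves as the analytic stand-in for an
#' empirical background when none can be built ("other genome" mode).
#'
#' @param m A [Motif-class].
#' @param baseFreqs Background base frequencies over (A, C, G, U); must sum
#'   to 1. Default uniform.
#' @param bin Raw-score discretization bin width.
#' @return A [ScoreDistribution-class].
#' @export
analyticScoreDistribution <- function(m, baseFreqs = rep(0.25, 4),
                                      bin = 1e-4) {
  stopifnot(length(baseFreqs) == 4L, abs(sum(baseFreqs) - 1) < 1e-6)
  L <- .logOdds(m)
  k <- ncol(L)
  rng <- .scoreRange(L)
  if (rng["max"] - rng["min"] < 1e-12) {
    return(new("ScoreDistribution", motifId = motifId(m),
               score = 1, prob = 1, bin = bin))
  }
  idx <- round(L / bin)  # 4 x k integer grid indices
  dist <- 1
  off <- 0
  for (j in seq_len(k)) {
    vals <- idx[, j]
    lo <- min(vals)
    width <- length(dist) + (max(vals) - lo)
    nd <- numeric(width)
    for (b in 1:4) {
      sh <- vals[b] - lo
      span <- (1L + sh):(sh + length(dist))
      nd[span] <- nd[span] + dist * baseFreqs[b]
    }
    dist <- nd
    off <- off + lo
  }
  keep <- dist > 0
  raw <- (off + which(keep) - 1) * bin
  # normalize by the grid's own achievable range so the best/worst k-mers
  # land exactly on 1 and 0 despite per-column rounding
  gridRng <- c(min = sum(apply(idx, 2L, min)),
               max = sum(apply(idx, 2L, max))) * bin
  score <- .normalizeScore(raw, gridRng)
  new("ScoreDistribution", motifId = motifId(m), score = score,
      prob = dist[keep], bin = bin)
}

#' Upper-tail probability of a ScoreDistribution
#'
#' \eqn{P(X \ge t)}, with a half-bin tolerance so that support points equal
#' to \code{t} up to discretization are included.
#'
#' @param dist A [ScoreDistribution-class].
#' @param t Score threshold(s).
#' @return Tail probability per threshold.
#' @export
tailProbability <- function(dist, t) {
  vapply(t, function(ti) sum(dist@prob[dist@score >= ti - 1e-9]),
         numeric(1L))
}

#' Theoretical anchor and suboptimal thresholds for a motif
#'
#' Match-score cutoffs derived from the exact analytic score distribution:
#' the smallest support score whose upper-tail probability is at most the
#' stringency p-value. Used when no genome-specific background model exists;
#' length and complexity of the motif enter through the distribution itself,
#' so higher-information motifs get higher absolute cutoffs.
#'
#' Returns \code{Inf} for a threshold no score can meet (e.g. an all-uniform
#' motif, where every k-mer scores 1 with probability 1): no site is then
#' callable at that stringency.
#'
#' @param m A [Motif-class].
#' @param stringency A [StringencyLevel-class] or tier name.
#' @param baseFreqs Background base frequencies (A, C, G, U).
#' @param bin Discretization bin width.
#' @return Named numeric: \code{significant} and \code{suboptimal} score
#'   thresholds, with \code{significant >= suboptimal}.
#' @export
theoreticalThreshold <- function(m, stringency = stringencyLevel("medium"),
                                 baseFreqs = rep(0.25, 4), bin = 1e-4) {
  if (is.character(stringency)) stringency <- stringencyLevel(stringency)
  dist <- analyticScoreDistribution(m, baseFreqs, bin)
  tail <- rev(cumsum(rev(dist@prob)))
  cut <- function(p) {
    ok <- which(tail <= p + 1e-12)
    if (!length(ok)) Inf else dist@score[ok[1]]
  }
  c(significant = cut(pSignificant(stringency)),
    suboptimal = cut(pSuboptimal(stringency)))
}
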