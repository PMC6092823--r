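#' @include profile.R
NULL

#' Consensus sequence with a frequency threshold
#'
#' Per column, the (optionally weighted) most frequent residue wins if its
#' frequency over all rows — gaps stay in the denominator but can never win
#' — strictly exceeds \code{threshold}; otherwise the column is reported as
#' \code{"X"}. A threshold just above 0.3 mirrors the common homology rule
#' of thumb that sequences over 30\% identical are considered homologous.
#' Ties are broken alphabetically and flagged.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param threshold winning frequency must strictly exceed this; in (0, 1].
#' @param weights optional per-sequence weights (normalized internally).
#' @return a \code{\linkS4class{ConsensusResult}}.
#' @examples
#' a <- ProteinAlignment(c(s1 = "AA", s2 = "AC", s3 = "CD", s4 = "CE"))
#' consensusSymbols(consensusSequence(a, 0.3))  # "A" (tie, flagged), "X"
#' @export
consensusSequence <- function(a, threshold = 0.3, weights = NULL) {
  stopifnot(is(a, "ProteinAlignment"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (!is.null(weights)) {
    if (length(weights) != nSeq(a) || any(weights < 0) || sum(weights) <= 0)
      stop("weights must be ", nSeq(a), " nonnegative values")
    weights <- weights / sum(weights)
  }
  alpha <- .residueAlphabet(a)
  cnt <- .columnCounts(a, weights = weights, alphabet = alpha)
  nTot <- colSums(cnt)
  syms <- character(ncol(cnt))
  winf <- numeric(ncol(cnt))
  tie <- logical(ncol(cnt))
  for (j in seq_len(ncol(cnt))) {
    aa <- cnt[alpha, j]
    f <- aa / nTot[j]
    top <- max(f, 0)
    winf[j] <- top
    if (top > threshold) {
      winners <- alpha[f == top]          # alphabet is sorted
      syms[j] <- winners[1L]
      tie[j] <- length(winners) > 1L
    } else {
      syms[j] <- "X"
    }
  }
  new("ConsensusResult", symbols = syms, threshold = threshold,
      winFreq = winf, tie = tie)
}

#' Similarity of each sequence to the consensus
#'
#' Fraction of informative columns (consensus not \code{"X"}) where the
#' sequence carries the consensus residue. Sequences with additional
#' domains or large insertions stand out with low values.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param cons a \code{\linkS4class{ConsensusResult}} for \code{a}.
#' @return named numeric vector in [0, 1], one entry per sequence.
#' @export
similarityToConsensus <- function(a, cons) {
  stopifnot(is(a, "ProteinAlignment"), is(cons, "ConsensusResult"))
  sym <- consensusSymbols(cons)
  if (length(sym) != nCol(a))
    stop("consensus length does not match the alignment")
  keep <- sym != "X"
  if (!any(keep)) stop("consensus uninformative: every column is 'X'")
  m <- a@seqs[, keep, drop = FALSE]
  hits <- m == matrix(sym[keep], nrow = nrow(m), ncol = sum(keep),
                      byrow = TRUE)
  setNames(rowMeans(hits), seqIds(a))
}

#' Pairwise p-distances between aligned sequences
#'
#' \eqn{d(i, j) = 1 - m / c} with \eqn{c} the number of columns where the
#' two rows are not both gaps and \eqn{m} the number of those columns with
#' identical symbols (a gap facing a residue counts as comparable and
#' non-identical). Pairs with no comparable column get \eqn{d = 1} with a
#' warning.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}} with at least 2 rows.
#' @return symmetric numeric matrix in [0, 1] with zero diagonal, dimnames
#'   = sequence ids.
#' @export
pairwiseDistances <- function(a) {
  stopifnot(is(a, "ProteinAlignment"))
  n <- nSeq(a)
  if (n < 2L) stop("at least 2 sequences required")
  m <- a@seqs
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(seqIds(a), seqIds(a)))
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- !(gap[i, ] & gap[j, ])
      nc <- sum(comp)
      if (nc == 0L) {
        d[i, j] <- d[j, i] <- 1
        warned <- TRUE
      } else {
        match <- sum(m[i, comp] == m[j, comp])
        d[i, j] <- d[j, i] <- 1 - match / nc
      }
    }
  }
  if (warned)
    warning("sequence pair(s) with no comparable columns; distance set to 1")
  d
}

#' Flag outlying values by the 1.5 IQR rule
#'
#' Uses R's default (type-7) quantiles: values below
#' \eqn{Q_1 - 1.5 \cdot IQR} (\code{direction = "low"}, for
#' consensus-similarity screening) or above \eqn{Q_3 + 1.5 \cdot IQR}
#' (\code{direction = "high"}, for mean pairwise distances) are flagged.
#' Constant input yields an empty flag set. Flagging is advisory: whether a
#' flagged sequence is removed, trimmed or kept is the user's call.
#'
#' @param values named numeric vector (at least 4 values).
#' @param direction \code{"low"} or \code{"high"}.
#' @return character vector of flagged names.
#' @examples
#' detectOutliers(c(a = 0.90, b = 0.91, c = 0.92, d = 0.50), "low")
#' @export
detectOutliers <- function(values, direction = c("low", "high")) {
  direction <- match.arg(direction)
  if (length(values) < 4L) stop("at least 4 values required")
  if (is.null(names(values))) names(values) <- seq_along(values)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  flag <- if (direction == "low") values < q[1L] - 1.5 * iqr
          else values > q[2L] + 1.5 * iqr
  names(values)[flag]
}

#' Outlier screening report for an alignment
#'
#' Combines the two detection routes — similarity to the consensus (low
#' tail flagged) and mean pairwise distance (high tail flagged) — into one
#' table, the basis for deciding which sequences to remove or trim before
#' re-running the analysis.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}} (>= 4 sequences for
#'   flagging).
#' @param threshold consensus threshold, see \code{\link{consensusSequence}}.
#' @param weights optional per-sequence weights for the consensus.
#' @return data.frame with columns \code{id}, \code{similarity},
#'   \code{meanDistance}, \code{lowSimilarity}, \code{highDistance}.
#' @export
outlierReport <- function(a, threshold = 0.3, weights = NULL) {
  cons <- consensusSequence(a, threshold = threshold, weights = weights)
  sim <- similarityToConsensus(a, cons)
  d <- pairwiseDistances(a)
  meanD <- rowSums(d) / (nSeq(a) - 1L)
  lowFlag <- highFlag <- character(0)
  if (nSeq(a) >= 4L) {
    lowFlag <- detectOutliers(sim, "low")
    highFlag <- detectOutliers(meanD, "high")
  }
  data.frame(id = seqIds(a),
             similarity = unname(sim),
             meanDistance = unname(meanD),
             lowSimilarity = seqIds(a) %in% lowFlag,
             highDistance = seqIds(a) %in% highFlag,
             stringsAsFactors = FALSE)
}
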