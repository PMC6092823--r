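#' @include AllClasses.R
NULL

## residue alphabet actually present (grouped alignments may use symbols
## outside the 20-letter code); gap and 'X' are never residues
.residueAlphabet <- function(a) {
  syms <- unique(as.vector(a@seqs))
  sort(setdiff(syms, c("-", "X")))
}

## counts (or weight sums) of every symbol per column; rows = residues
## in 'alphabet' order, then '-', then 'X'
.columnCounts <- function(a, weights = NULL, alphabet = .residueAlphabet(a)) {
  m <- a@seqs
  syms <- c(alphabet, "-", "X")
  if (is.null(weights)) weights <- rep(1, nrow(m))
  out <- matrix(0, nrow = length(syms), ncol = ncol(m),
                dimnames = list(syms, NULL))
  for (s in syms) {
    hit <- m == s
    out[s, ] <- if (nrow(m) == 1L) weights[1] * hit else colSums(weights * hit)
  }
  out
}

#' Symbol counts and frequencies of one alignment column
#'
#' @slot column 1-based column index.
#' @slot counts named numeric vector of symbol counts (residues, then
#'   \code{"-"}, then \code{"X"}).
#' @slot nTotal total number of rows.
#' @slot nAA number of rows carrying a residue (gaps and \code{"X"}
#'   excluded).
#' @slot p residue frequencies with gaps (and \code{"X"}) included in the
#'   denominator, i.e. \code{counts / nTotal}.
#' @slot nTypes number of distinct residues present (gaps excluded).
#' @export
setClass("ColumnProfile",
         representation(column = "integer", counts = "numeric",
                        nTotal = "numeric", nAA = "numeric",
                        p = "numeric", nTypes = "integer"))

setMethod("show", "ColumnProfile", function(object) {
  cat(sprintf("ColumnProfile [col %d]: %d residue type(s), %g/%g gapless\n",
              object@column, object@nTypes, object@nAA, object@nTotal))
})

#' Profile a single alignment column
#'
#' Returns the symbol counts of column \code{col} together with the two
#' frequency views used by the scores: \code{p}, the residue frequencies
#' with gaps included in the denominator, and \code{nTypes}, the number of
#' distinct residues with gaps excluded.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param col 1-based column index.
#' @return a \code{\linkS4class{ColumnProfile}}.
#' @examples
#' a <- ProteinAlignment(c(s1 = "A", s2 = "A", s3 = "A", s4 = "-"))
#' columnProfile(a, 1)@p["A"]   # 0.75: gaps stay in the denominator
#' @export
columnProfile <- function(a, col) {
  stopifnot(is(a, "ProteinAlignment"))
  col <- as.integer(col)
  if (length(col) != 1L || is.na(col) || col < 1L || col > nCol(a))
    stop("column index out of range 1..", nCol(a))
  alpha <- .residueAlphabet(a)
  cnt <- .columnCounts(a, alphabet = alpha)[, col]
  nTot <- sum(cnt)
  aa <- cnt[alpha]
  new("ColumnProfile",
      column = col,
      counts = cnt,
      nTotal = nTot,
      nAA = sum(aa),
      p = aa / nTot,
      nTypes = sum(aa > 0))
}
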