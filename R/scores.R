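#' @include weighting.R
NULL

## Shannon entropy (nats) of a nonnegative weight vector, 0 for empty input
.entropy <- function(x) {
  x <- x[x > 0]
  if (!length(x)) return(0)
  q <- x / sum(x)
  -sum(q * log(q))
}

#' Per-column conservation/variability scores
#'
#' Computes one of the four frequency-based metrics for every alignment
#' column. All four are reported in variability orientation (larger = more
#' variable):
#' \describe{
#'   \item{shannon}{\eqn{H = -\sum_a q_a \ln q_a} over the residue
#'     frequencies \eqn{q} renormalized without gaps; reported in nats.}
#'   \item{schneider}{\eqn{H / \ln 20}, i.e. Shannon entropy normalized to
#'     [0, 1] by the 20-letter maximum (the denominator is fixed at
#'     \eqn{\ln 20} even for alignments with fewer sequences than residue
#'     types).}
#'   \item{kabat}{\eqn{V = k N / n_1}: number of distinct residues times
#'     the number of residue-carrying rows over the count of the most
#'     common residue. Equals 1 exactly on columns invariant over their
#'     non-gap rows.}
#'   \item{escore}{a min-max normalized score built from the dominant
#'     residue frequency with gaps kept in the denominator:
#'     \eqn{P_i = \max(p_i) / n_i}, \eqn{P^{norm}_i = P_i / \max_j P_j},
#'     \eqn{E_i = -\ln P^{norm}_i / \max_j(-\ln P^{norm}_j)}. Gaps lower
#'     \eqn{\max(p_i)} without entering the entropy-style term itself, so
#'     gap-heavy columns stay distinguishable; \eqn{E \in [0,1]}, an
#'     invariant gapless column scores 0 and the most variable column
#'     scores 1. If every column has the same \eqn{P} the score is
#'     identically 0.}
#' }
#'
#' Sequence weights (e.g. \code{\link{henikoffWeights}}) replace raw counts
#' with weight sums. Pseudo-counts (\code{\link{pseudocountFrequencies}})
#' adjust the residue frequencies before scoring; the number of residue
#' types \eqn{k}/\eqn{n_i} always comes from the observed counts. All-gap
#' columns yield \code{NaN} (with a warning) and are excluded from the
#' E-score normalization maxima.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}} with at least 2 rows.
#' @param metric one of \code{"shannon"}, \code{"schneider"},
#'   \code{"kabat"}, \code{"escore"}.
#' @param weights optional per-sequence weights (any positive vector; it is
#'   normalized to sum to 1).
#' @param pseudocounts \code{NULL} (off), \code{TRUE} (defaults), or a list
#'   with elements \code{B} (total pseudo-mass; default \code{5 * k} per
#'   column) and \code{background} (conditional matrix; default
#'   \code{\link{blosumBackground}()}).
#' @return a \code{\linkS4class{ConservationProfile}}.
#' @examples
#' a <- ProteinAlignment(c(s1 = "AAA", s2 = "AAA", s3 = "AAC", s4 = "A-C"))
#' scoreValues(scoreConservation(a, "escore"))
#' @export
scoreConservation <- function(a,
                              metric = c("shannon", "schneider", "kabat",
                                         "escore"),
                              weights = NULL, pseudocounts = NULL) {
  stopifnot(is(a, "ProteinAlignment"))
  metric <- match.arg(metric)
  if (nSeq(a) < 2L) stop("at least 2 sequences required")
  if (!is.null(weights)) {
    if (length(weights) != nSeq(a) || any(weights < 0) || sum(weights) <= 0)
      stop("weights must be ", nSeq(a), " nonnegative values")
    weights <- weights / sum(weights)
  }
  alpha <- .residueAlphabet(a)
  cnt <- .columnCounts(a, weights = weights, alphabet = alpha)
  aa <- cnt[alpha, , drop = FALSE]
  nTot <- colSums(cnt)
  nAA <- colSums(aa)
  nTypes <- colSums(aa > 0)
  allGap <- nAA == 0

  pc <- NULL
  if (isTRUE(pseudocounts)) pc <- list()
  else if (is.list(pseudocounts)) pc <- pseudocounts
  if (!is.null(pc)) {
    B <- if (is.null(pc$B)) NULL else pc$B
    bg <- if (is.null(pc$background)) blosumBackground() else pc$background
    qMat <- .pcFreqMatrix(cnt, alpha, B, bg, "aa")   # residues-only denom
    pMat <- .pcFreqMatrix(cnt, alpha, B, bg, "all")  # gaps in denom
  } else {
    qMat <- sweep(aa, 2L, ifelse(nAA > 0, nAA, 1), "/")
    qMat[, allGap] <- NA_real_
    pMat <- sweep(aa, 2L, ifelse(nTot > 0, nTot, 1), "/")
    pMat[, allGap] <- NA_real_
  }

  vals <- switch(metric,
    shannon = apply(qMat, 2L, function(q)
      if (anyNA(q)) NaN else .entropy(q)),
    schneider = apply(qMat, 2L, function(q)
      if (anyNA(q)) NaN else .entropy(q)) / log(20),
    kabat = {
      f1 <- apply(qMat, 2L, function(q) if (anyNA(q)) NaN else max(q))
      nTypes / f1
    },
    escore = {
      P <- apply(pMat, 2L, function(p) if (anyNA(p)) NaN else max(p)) /
        ifelse(nTypes > 0, nTypes, NA_real_)
      ok <- is.finite(P)
      E <- rep(NaN, length(P))
      if (any(ok)) {
        Pn <- P / max(P[ok])
        nl <- -log(Pn) + 0   # + 0 normalizes IEEE -0
        top <- max(nl[ok])
        E[ok] <- if (top > 0) nl[ok] / top else 0
      }
      E
    })
  vals[allGap] <- NaN
  if (any(allGap))
    warning("all-gap column(s) scored NaN: ",
            paste(utils::head(which(allGap), 5), collapse = ", "))
  new("ConservationProfile", metric = metric, values = unname(vals),
      orientation = "variability")
}

#' Landgraf conservation index
#'
#' Weighted sum of asymmetric substitution-matrix distances over the
#' residue pairs of each column:
#' \eqn{L = \sum_{j \ne k} w_j \, d(a_j \to a_k) / (N (N - 1))} with
#' \eqn{d(a \to b) = S(a,a) - S(a,b)}, where \eqn{S} is a similarity matrix
#' (default the bundled Gonnet PAM250 matrix, whose off-diagonal
#' substitution costs are asymmetric after the self-score shift) and
#' \eqn{N} the number of residue-carrying rows in the column. Gapped and
#' \code{'X'} rows are excluded from the pair set. Variability orientation:
#' \eqn{L = 0} exactly on invariant columns.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param weights per-sequence weights summing to 1; default uniform.
#' @param matrix square similarity matrix with residue dimnames; default
#'   \code{\link{gonnetMatrix}()}.
#' @return a \code{\linkS4class{ConservationProfile}}.
#' @references Landgraf R, Xenarios I, Eisenberg D (2001) Three-dimensional
#'   cluster analysis identifies interfaces and functional residue clusters
#'   in proteins. J Mol Biol 307:1487-1502.
#' @export
scoreLandgraf <- function(a, weights = NULL, matrix = gonnetMatrix()) {
  stopifnot(is(a, "ProteinAlignment"))
  if (nSeq(a) < 2L) stop("at least 2 sequences required")
  if (is.null(weights)) weights <- rep(1 / nSeq(a), nSeq(a))
  if (length(weights) != nSeq(a) || any(weights < 0))
    stop("weights must be ", nSeq(a), " nonnegative values")
  weights <- weights / sum(weights)
  m <- a@seqs
  vals <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    res <- m[, j]
    keep <- !res %in% c("-", "X")
    if (!any(keep)) { vals[j] <- NaN; next }
    r <- res[keep]
    w <- weights[keep]
    if (length(bad <- setdiff(unique(r), rownames(matrix))))
      stop("symbol(s) absent from substitution matrix: ",
           paste(bad, collapse = ", "))
    N <- length(r)
    if (N < 2L) { vals[j] <- 0; next }
    S <- matrix[r, r, drop = FALSE]
    d <- diag(S) - S                 # d[j,k] = S(aj,aj) - S(aj,ak)
    vals[j] <- sum(w * rowSums(d)) / (N * (N - 1))
  }
  if (any(is.nan(vals)))
    warning("all-gap column(s) scored NaN")
  new("ConservationProfile", metric = "landgraf", values = vals,
      orientation = "variability")
}

#' Bundled Gonnet PAM250 substitution matrix
#'
#' Reads the Gonnet, Cohen & Benner (1992) amino-acid similarity matrix
#' shipped with the package (10*log10-odds units at 250 PAM).
#'
#' @return 20 x 20 numeric matrix with residue dimnames.
#' @export
gonnetMatrix <- function() {
  readSubstitutionMatrix(system.file("extdata", "gonnet250.txt",
                                     package = "MSAcons", mustWork = TRUE))
}

#' Read a substitution matrix in NCBI square plain-text format
#'
#' Lines starting with \code{#} are comments; the first non-comment line
#' lists the column symbols, each following line a row symbol and its
#' values.
#'
#' @param path file path.
#' @return square numeric matrix with symbol dimnames.
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty substitution matrix file: ", path)
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  rows <- vapply(body, `[`, character(1), 1L)
  vals <- t(vapply(body, function(x) as.numeric(x[-1L]),
                   numeric(length(cols))))
  dimnames(vals) <- list(rows, cols)
  if (!setequal(rows, cols)) stop("matrix is not square over its symbols")
  vals[rows, rows]
}

#' Map an alignment onto a reduced (grouped) alphabet
#'
#' Replaces every residue by its physicochemical group symbol (e.g.
#' hydrophobic, charged, ...), keeping gaps as gaps. The result is a
#' regular alignment over the group alphabet and is accepted unchanged by
#' every scoring operation, enabling the "grouping mode" analysis of
#' property conservation rather than identity conservation.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param scheme named character vector mapping each of the 20 residues to
#'   a single-character group symbol (e.g. from
#'   \code{\link{readGroupingScheme}}).
#' @return a \code{\linkS4class{ProteinAlignment}} over the group alphabet.
#' @examples
#' sch <- setNames(rep("h", 20), c("A","C","D","E","F","G","H","I","K","L",
#'                                 "M","N","P","Q","R","S","T","V","W","Y"))
#' sch[c("K", "R")] <- "+"
#' alnStrings(applyGrouping(ProteinAlignment(c(s1 = "AVLK", s2 = "AVLR")),
#'                          sch))
#' @export
applyGrouping <- function(a, scheme) {
  stopifnot(is(a, "ProteinAlignment"))
  if (is.null(names(scheme))) stop("grouping scheme must be named by residue")
  syms <- setdiff(unique(as.vector(a@seqs)), c("-", "X"))
  if (length(bad <- setdiff(syms, names(scheme))))
    stop("grouping scheme lacks symbol(s): ", paste(bad, collapse = ", "))
  if (any(nchar(scheme) != 1L)) stop("group symbols must be single characters")
  m <- a@seqs
  full <- c(scheme, "-" = "-", X = "X")
  m[] <- full[m]
  out <- new("ProteinAlignment", seqs = m, colMap = a@colMap)
  validObject(out)
  out
}

#' Read a grouping scheme from a two-column text file
#'
#' Whitespace-delimited lines of \code{residue group}; \code{#} comments
#' allowed.
#'
#' @param path file path.
#' @return named character vector (residue -> group symbol).
#' @export
readGroupingScheme <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) < 2L)) stop("each line needs 'residue group'")
  setNames(vapply(parts, `[`, character(1), 2L),
           toupper(vapply(parts, `[`, character(1), 1L)))
}
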