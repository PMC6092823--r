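#' @include upgma.R structure-map.R
NULL

#' Kolmogorov-Smirnov comparison of a compartment against the rest
#'
#' Two-sample KS test between the conservation scores of the compartment
#' columns and those of the remaining columns:
#' \eqn{D = \sup_x |F_1(x) - F_2(x)|} over the two empirical CDFs, with the
#' asymptotic Kolmogorov p-value (effective size \eqn{n_1 n_2 / (n_1 +
#' n_2)}), the usual choice at the scale of a few hundred alignment
#' columns. Under the null the two sets of columns evolve at the same
#' rate. NaN columns (all-gap) are excluded from both samples.
#'
#' @param profile a \code{\linkS4class{ConservationProfile}}.
#' @param compartmentCols integer vector of compartment column indices.
#' @param restCols columns forming the comparison set; default all other
#'   columns of the profile.
#' @return a \code{\linkS4class{KSResult}}.
#' @export
ksCompare <- function(profile, compartmentCols, restCols = NULL) {
  stopifnot(is(profile, "ConservationProfile"))
  v <- profile@values
  compartmentCols <- unique(as.integer(compartmentCols))
  if (any(compartmentCols < 1L | compartmentCols > length(v)))
    stop("compartment columns out of range")
  if (is.null(restCols))
    restCols <- setdiff(seq_along(v), compartmentCols)
  restCols <- setdiff(unique(as.integer(restCols)), compartmentCols)
  if (!length(restCols)) stop("empty complement: nothing to compare against")
  x <- v[compartmentCols]; x <- x[is.finite(x)]
  y <- v[restCols]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 finite scores in each sample")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  new("KSResult", D = unname(kt$statistic), p = min(1, unname(kt$p.value)),
      n1 = length(x), n2 = length(y))
}

#' Least and most variable positions of a column set
#'
#' Ranks the finite scores within \code{cols} respecting the metric's
#' orientation (for a conservation-oriented metric the largest scores are
#' the least variable) and returns the k extreme columns on each side.
#' Ties are broken towards the lower column index.
#'
#' @param profile a \code{\linkS4class{ConservationProfile}}.
#' @param cols integer vector of column indices (non-empty).
#' @param k number of positions per side (>= 1); truncated with a warning
#'   if the set is smaller.
#' @return list with integer vectors \code{least} and \code{most}
#'   (variable), each of length at most \code{k}.
#' @export
extremePositions <- function(profile, cols, k = 1L) {
  stopifnot(is(profile, "ConservationProfile"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  cols <- unique(as.integer(cols))
  if (!length(cols)) stop("'cols' must be non-empty")
  v <- profile@values[cols]
  keep <- is.finite(v)
  cols <- cols[keep]; v <- v[keep]
  if (!length(cols)) stop("no finite scores in 'cols'")
  if (k > length(cols)) {
    warning("k exceeds available columns; truncated to ", length(cols))
    k <- length(cols)
  }
  ## ascending variability regardless of stored orientation
  vv <- if (profile@orientation == "variability") v else -v
  ordAsc <- order(vv, cols)
  ordDesc <- order(-vv, cols)
  list(least = cols[ordAsc][seq_len(k)],
       most = cols[ordDesc][seq_len(k)])
}

#' Assemble the per-position profile table
#'
#' One record per alignment column: 1-based column index, reference
#' residue number (empty at gap columns of the reference), consensus
#' symbol, one column per metric, one logical flag per compartment (TRUE
#' exactly on its mapped columns) and the compartments' numeric features
#' attached at their mapped columns.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param profiles list of \code{\linkS4class{ConservationProfile}}
#'   objects computed on \code{a}.
#' @param map optional \code{\linkS4class{ResidueMap}}.
#' @param compartments list of \code{\linkS4class{Compartment}} objects
#'   (requires \code{map}).
#' @param consensus optional \code{\linkS4class{ConsensusResult}}.
#' @return data.frame with \code{nCol(a)} rows, ready for
#'   \code{\link{writeProfileCSV}}.
#' @export
assembleProfileTable <- function(a, profiles = list(), map = NULL,
                                 compartments = list(), consensus = NULL) {
  stopifnot(is(a, "ProteinAlignment"))
  nc <- nCol(a)
  tbl <- data.frame(column = seq_len(nc))
  if (!is.null(map)) {
    stopifnot(is(map, "ResidueMap"))
    ref <- rep(NA_integer_, nc)
    ref[map@columns] <- seq_along(map@columns)
    tbl$ref_residue <- ref
  }
  if (!is.null(consensus)) {
    stopifnot(is(consensus, "ConsensusResult"))
    if (length(consensus@symbols) != nc)
      stop("consensus length does not match the alignment")
    tbl$consensus <- consensus@symbols
  }
  if (length(profiles)) {
    for (p in profiles) {
      stopifnot(is(p, "ConservationProfile"))
      if (length(p@values) != nc)
        stop("profile '", p@metric, "' length does not match the alignment")
      tbl[[p@metric]] <- p@values
    }
  }
  if (length(compartments)) {
    if (is.null(map)) stop("compartment flags require a residue map")
    for (comp in compartments) {
      stopifnot(is(comp, "Compartment"))
      cols <- compartmentColumns(map, comp, a = NULL)
      flag <- rep(FALSE, nc)
      flag[cols] <- TRUE
      tbl[[paste0("in_", comp@name)]] <- flag
      feats <- setdiff(colnames(comp@residues), c("number", "name"))
      for (fc in feats) {
        v <- rep(NA_real_, nc)
        v[cols] <- comp@residues[[fc]]
        tbl[[paste0(comp@name, "_", fc)]] <- v
      }
    }
  }
  tbl
}
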