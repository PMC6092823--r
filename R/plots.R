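#' @include compare-stats.R
NULL

.openDevice <- function(file, width = 9, height = 5) {
  ext <- tolower(sub(".*\\.", "", file))
  switch(ext,
         png = grDevices::png(file, width = width, height = height,
                              units = "in", res = 120),
         svg = grDevices::svg(file, width = width, height = height),
         pdf = grDevices::pdf(file, width = width, height = height),
         stop("unsupported image format: .", ext, " (use png/svg/pdf)"))
}

#' Variability profile plot with compartment markers
#'
#' Bar chart of a conservation profile over all alignment columns, with
#' each compartment's columns marked by its own point symbol above the
#' bars. Returns the plotted numbers so figures remain testable without
#' image comparison.
#'
#' @param profile a \code{\linkS4class{ConservationProfile}}.
#' @param compartments named list of integer column vectors.
#' @param file optional output image path (png/svg/pdf); default plots to
#'   the active device.
#' @return data.frame of the plotted values (column, score, one logical
#'   per compartment), invisibly.
#' @export
plotProfile <- function(profile, compartments = list(), file = NULL) {
  stopifnot(is(profile, "ConservationProfile"))
  v <- profile@values
  if (!is.null(file)) { .openDevice(file); on.exit(grDevices::dev.off()) }
  bp <- graphics::barplot(v, border = NA, col = "grey40",
                          xlab = "alignment column",
                          ylab = paste0(profile@metric, " (",
                                        profile@orientation, ")"),
                          names.arg = rep("", length(v)))
  top <- max(v[is.finite(v)], 0)
  out <- data.frame(column = seq_along(v), score = v)
  i <- 0L
  for (nm in names(compartments)) {
    i <- i + 1L
    cols <- compartments[[nm]]
    graphics::points(bp[cols], rep(top * (1 + 0.06 * i), length(cols)),
                     pch = i, col = i + 1L)
    out[[paste0("in_", nm)]] <- seq_along(v) %in% cols
  }
  if (length(compartments))
    graphics::legend("topright", legend = names(compartments),
                     pch = seq_along(compartments),
                     col = seq_along(compartments) + 1L, bty = "n")
  invisible(out)
}

#' Residue composition bars for selected columns
#'
#' Stacked relative-frequency bars (gaps and unknowns included) for a set
#' of alignment columns.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param cols column indices.
#' @param file optional output image path.
#' @return data.frame of symbol frequencies per column, invisibly.
#' @export
plotComposition <- function(a, cols, file = NULL) {
  stopifnot(is(a, "ProteinAlignment"))
  cols <- as.integer(cols)
  if (any(cols < 1L | cols > nCol(a))) stop("columns out of range")
  cnt <- .columnCounts(a)[, cols, drop = FALSE]
  freq <- sweep(cnt, 2L, colSums(cnt), "/")
  colnames(freq) <- cols
  if (!is.null(file)) { .openDevice(file); on.exit(grDevices::dev.off()) }
  keep <- rowSums(freq) > 0
  graphics::barplot(freq[keep, , drop = FALSE], col = grDevices::rainbow(sum(keep)),
                    xlab = "alignment column", ylab = "frequency",
                    legend.text = rownames(freq)[keep],
                    args.legend = list(x = "topright", bty = "n", cex = 0.6))
  invisible(as.data.frame(t(freq)))
}

#' Empirical CDF overlay: compartment versus rest
#'
#' Plots the ECDF of the compartment columns' scores against the ECDF of
#' the remaining columns — the visual counterpart of
#' \code{\link{ksCompare}} — and annotates the k least and most variable
#' compartment positions.
#'
#' @param profile a \code{\linkS4class{ConservationProfile}}.
#' @param compartmentCols compartment column indices.
#' @param restCols comparison columns; default all others.
#' @param k number of extreme positions to annotate (0 to disable).
#' @param file optional output image path.
#' @return data.frame of ECDF evaluation points (score, ecdf, sample),
#'   invisibly.
#' @export
plotCDF <- function(profile, compartmentCols, restCols = NULL, k = 3L,
                    file = NULL) {
  stopifnot(is(profile, "ConservationProfile"))
  v <- profile@values
  compartmentCols <- unique(as.integer(compartmentCols))
  if (is.null(restCols)) restCols <- setdiff(seq_along(v), compartmentCols)
  x <- v[compartmentCols]; x <- x[is.finite(x)]
  y <- v[restCols]; y <- y[is.finite(y)]
  if (!is.null(file)) { .openDevice(file); on.exit(grDevices::dev.off()) }
  graphics::plot(stats::ecdf(y), col = "grey50", main = "",
                 xlab = paste0(profile@metric, " score"), ylab = "ECDF")
  graphics::plot(stats::ecdf(x), col = "darkgreen", add = TRUE)
  graphics::legend("bottomright", legend = c("compartment", "rest"),
                   col = c("darkgreen", "grey50"), lty = 1, bty = "n")
  if (k > 0L) {
    ex <- extremePositions(profile, compartmentCols, k = min(k, length(x)))
    graphics::abline(v = v[ex$least], col = "red", lty = 3)
    graphics::abline(v = v[ex$most], col = "blue", lty = 3)
  }
  invisible(rbind(
    data.frame(score = sort(x), ecdf = seq_along(x) / length(x),
               sample = "compartment"),
    data.frame(score = sort(y), ecdf = seq_along(y) / length(y),
               sample = "rest")))
}

#' Score-score scatter plot
#'
#' Compares two conservation metrics column-by-column; with no agreed
#' gold standard for conservation, such scatter plots are the practical
#' way to judge how two metrics disagree on a given alignment.
#'
#' @param p1,p2 \code{\linkS4class{ConservationProfile}} objects over the
#'   same alignment.
#' @param file optional output image path.
#' @return data.frame (column, score1, score2), invisibly.
#' @export
plotScoreScatter <- function(p1, p2, file = NULL) {
  stopifnot(is(p1, "ConservationProfile"), is(p2, "ConservationProfile"))
  if (length(p1@values) != length(p2@values))
    stop("profiles have different lengths")
  if (!is.null(file)) { .openDevice(file, width = 6, height = 6)
    on.exit(grDevices::dev.off()) }
  graphics::plot(p1@values, p2@values, pch = 16, cex = 0.6,
                 col = grDevices::adjustcolor("steelblue", 0.7),
                 xlab = p1@metric, ylab = p2@metric)
  invisible(data.frame(column = seq_along(p1@values),
                       score1 = p1@values, score2 = p2@values))
}
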