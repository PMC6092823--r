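#' @include AllClasses.R
NULL

## symbols kept verbatim on ingest; everything else becomes 'X'
.KNOWN <- c(.AA20, "-", "X")

.normalizeRow <- function(s) {
  s <- chartr(".", "-", toupper(s))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ch[!ch %in% .KNOWN] <- "X"
  paste0(ch, collapse = "")
}

#' Construct a protein alignment from strings or a character matrix
#'
#' Symbols are uppercased, \code{"."} gaps are normalized to \code{"-"} and
#' any letter outside the 20-residue alphabet (B, Z, J, U, O, \code{*}, ...)
#' is mapped to \code{"X"}, which is excluded from residue counts but still
#' occupies a row slot in every column total. Set \code{normalize = FALSE}
#' to keep symbols verbatim (used internally for grouped alphabets).
#'
#' @param x named character vector of equal-length aligned strings, or a
#'   character matrix of single symbols with rownames.
#' @param normalize apply symbol normalization (default \code{TRUE}).
#' @return a \code{\linkS4class{ProteinAlignment}}.
#' @examples
#' ProteinAlignment(c(s1 = "ac.d", s2 = "ACAD"))
#' @export
ProteinAlignment <- function(x, normalize = TRUE) {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (is.null(names(x)))
      names(x) <- paste0("seq", seq_along(x))
    if (normalize) x <- vapply(x, .normalizeRow, character(1))
    len <- nchar(x)
    if (length(unique(len)) > 1L) {
      bad <- names(x)[len != len[1L]][1L]
      stop("ragged alignment: sequence '", bad,
           "' has length ", nchar(x[bad]), ", expected ", len[1L])
    }
    m <- matrix("", nrow = length(x), ncol = len[1L],
                dimnames = list(names(x), NULL))
    if (len[1L] > 0L) {
      rows <- strsplit(x, "", fixed = TRUE)
      for (i in seq_along(rows)) m[i, ] <- rows[[i]]
    }
  }
  if (normalize && is.matrix(x)) {
    m[] <- vapply(m, function(c) {
      c <- chartr(".", "-", toupper(c))
      if (c %in% .KNOWN) c else "X"
    }, character(1))
  }
  new("ProteinAlignment", seqs = m, colMap = seq_len(ncol(m)))
}

#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file through Biostrings and normalizes
#' symbols (uppercase; \code{"."} to \code{"-"}; non-standard letters to
#' \code{"X"}). Rows must all have the same length and ids must be unique.
#'
#' @param path path to the alignment file.
#' @param format \code{"fasta"} (default) or \code{"clustal"}.
#' @return a \code{\linkS4class{ProteinAlignment}}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "AC-D", ">s2", "ACAD"), fa)
#' readAlignment(fa)
#' @export
readAlignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L) stop("empty alignment file: ", path)
    s <- as.character(x)
    ## FASTA headers: id = first whitespace-delimited token
    names(s) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  } else {
    x <- Biostrings::unmasked(
      Biostrings::readAAMultipleAlignment(path, format = "clustal"))
    if (length(x) == 0L) stop("empty alignment file: ", path)
    s <- as.character(x)
  }
  if (anyDuplicated(names(s)))
    stop("duplicate sequence id: ", names(s)[duplicated(names(s))][1L])
  ProteinAlignment(s)
}

#' Drop sequences and/or columns from an alignment
#'
#' Returns a new alignment; the input is untouched. Original column indices
#' survive in \code{\link{columnProvenance}}, so positions reported after
#' trimming can be traced back to the alignment as read.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param dropIds sequence ids to remove.
#' @param dropCols column indices (1-based, current numbering) to remove.
#' @return a \code{\linkS4class{ProteinAlignment}}.
#' @examples
#' a <- ProteinAlignment(c(s1 = "AC-D", s2 = "ACAD", s3 = "ACCD"))
#' alnStrings(trimAlignment(a, dropCols = 2))
#' @export
trimAlignment <- function(a, dropIds = character(0), dropCols = integer(0)) {
  stopifnot(is(a, "ProteinAlignment"))
  if (length(bad <- setdiff(dropIds, seqIds(a))))
    stop("unknown sequence id(s): ", paste(bad, collapse = ", "))
  dropCols <- as.integer(dropCols)
  if (length(dropCols) && (any(dropCols < 1L) || any(dropCols > nCol(a))))
    stop("column indices out of range 1..", nCol(a))
  keepR <- !seqIds(a) %in% dropIds
  keepC <- !seq_len(nCol(a)) %in% dropCols
  if (sum(keepR) < 2L) stop("trimming would leave fewer than 2 sequences")
  if (sum(keepC) < 1L) stop("trimming would leave no columns")
  new("ProteinAlignment",
      seqs = a@seqs[keepR, keepC, drop = FALSE],
      colMap = a@colMap[keepC])
}

#' Write a per-position profile table as CSV
#'
#' RFC-4180 CSV with a header row and one data row per alignment column.
#' Missing values (e.g. the reference residue number at a gap column) are
#' written as empty cells, not \code{"NA"} text, so the file round-trips
#' through \code{\link{readProfileCSV}} value-for-value.
#'
#' @param tbl a profile data.frame, e.g. from
#'   \code{\link{assembleProfileTable}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProfileCSV <- function(tbl, path) {
  stopifnot(is.data.frame(tbl))
  utils::write.csv(tbl, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeProfileCSV
#' @export
readProfileCSV <- function(path) {
  if (!file.exists(path)) stop("profile CSV not found: ", path)
  utils::read.csv(path, na.strings = "", check.names = FALSE)
}
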