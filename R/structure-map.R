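#' @include AllClasses.R
NULL

.toOneLetter <- function(x) {
  x <- toupper(x)
  three <- setNames(names(.AA3), .AA3)
  ifelse(nchar(x) == 3L, unname(three[x]), x)
}

#' Read a compartment table
#'
#' Parses the plain-text residue table describing one functional
#' compartment (tunnel, gate, binding site, ...): whitespace- or
#' tab-delimited with a header line, columns \code{number} (residue
#' number), \code{name} (1- or 3-letter residue code) and zero or more
#' numeric feature columns (B-factors, RMSF, solvent accessibility, ...).
#'
#' @param path file path.
#' @param name compartment name; defaults to the file name without
#'   extension.
#' @return a \code{\linkS4class{Compartment}}.
#' @export
readCompartmentTable <- function(path, name = NULL) {
  if (!file.exists(path)) stop("compartment table not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          fill = TRUE)
  if (ncol(df) < 2L) stop("compartment table needs number and name columns")
  colnames(df)[1:2] <- c("number", "name")
  df$number <- as.integer(df$number)
  if (anyNA(df$number)) stop("non-integer residue number in table")
  if (anyDuplicated(df$number))
    stop("duplicate residue number: ",
         df$number[duplicated(df$number)][1L])
  one <- .toOneLetter(df$name)
  if (anyNA(one) || !all(one %in% c(.AA20, "X")))
    stop("invalid residue name(s): ",
         paste(unique(df$name[is.na(one) | !one %in% c(.AA20, "X")]),
               collapse = ", "))
  for (fc in setdiff(colnames(df), c("number", "name"))) {
    v <- df[[fc]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
      if (any(!is.na(v) & v != "" & is.na(num))) {
        bad <- which(!is.na(v) & v != "" & is.na(num))[1L]
        stop("non-numeric feature '", fc, "' in row ", bad)
      }
      df[[fc]] <- num
    }
    if (anyNA(df[[fc]]))
      warning("missing value(s) in feature '", fc, "'")
  }
  new("Compartment", name = name, residues = df)
}

#' Missing residues from a PDB file's REMARK 465 section
#'
#' Returns the author residue numbers listed as missing (not located in
#' the experiment) for one chain. Only the REMARK 465 records are read;
#' coordinates are never touched. Records carrying an insertion code are
#' rejected.
#'
#' @param pdbPath path to a PDB-format file.
#' @param chain chain identifier (single character).
#' @return data.frame with columns \code{resname} (3-letter) and
#'   \code{number}; zero rows when the chain has no missing residues.
#' @export
readMissingResidues <- function(pdbPath, chain) {
  if (!file.exists(pdbPath)) stop("PDB file not found: ", pdbPath)
  lines <- grep("^REMARK 465", readLines(pdbPath), value = TRUE)
  ## residue records: [model] RESNAME CHAIN SEQNUM[ICODE]
  pat <- "^REMARK 465\\s+(?:\\d+\\s+)?([A-Z]{3})\\s+([A-Za-z0-9])\\s+(-?\\d+)([A-Za-z]?)\\s*$"
  hit <- regmatches(lines, regexec(pat, lines))
  hit <- hit[lengths(hit) == 5L]
  if (!length(hit))
    return(data.frame(resname = character(0), number = integer(0)))
  resname <- vapply(hit, `[`, character(1), 2L)
  ch <- vapply(hit, `[`, character(1), 3L)
  num <- as.integer(vapply(hit, `[`, character(1), 4L))
  icode <- vapply(hit, `[`, character(1), 5L)
  keep <- ch == chain
  if (any(keep & nzchar(icode)))
    stop("REMARK 465 insertion codes are not supported (chain ", chain, ")")
  data.frame(resname = resname[keep], number = num[keep],
             stringsAsFactors = FALSE)
}

#' Correct compartment numbering for unresolved residues
#'
#' Structure-analysis tools number residues sequentially over the residues
#' actually observed in the crystal, while sequence analyses use author
#' numbering. This converts a compartment from sequential (observed)
#' numbering to author numbering by skipping the residues that the PDB
#' file's REMARK 465 section lists as missing for the chain: with missing
#' residues \{5, 6\}, sequential index 5 becomes author residue 7. If the
#' chain has no missing residues the compartment is returned unchanged
#' (with a message).
#'
#' @param comp a \code{\linkS4class{Compartment}} in sequential numbering.
#' @param pdbPath path to the PDB file.
#' @param chain chain identifier.
#' @return a \code{\linkS4class{Compartment}} in author numbering.
#' @seealso \code{\link{sequentialToAuthor}} and its inverse
#'   \code{\link{authorToSequential}}.
#' @export
correctNumbering <- function(comp, pdbPath, chain) {
  stopifnot(is(comp, "Compartment"))
  miss <- readMissingResidues(pdbPath, chain)
  if (nrow(miss) == 0L) {
    message("no missing residues recorded for chain ", chain,
            "; numbering left unchanged")
    return(comp)
  }
  df <- comp@residues
  df$number <- sequentialToAuthor(df$number, miss$number)
  new("Compartment", name = comp@name, residues = df)
}

#' Convert between sequential (observed) and author residue numbering
#'
#' \code{sequentialToAuthor(i, missing)} returns, for each sequential index
#' \code{i}, the i-th author residue number not in \code{missing} (author
#' numbering assumed to start at 1). \code{authorToSequential} is its
#' inverse; author numbers that are themselves missing yield an error.
#'
#' @param idx integer vector of indices/numbers to convert.
#' @param missing integer vector of missing author residue numbers.
#' @return integer vector of converted numbers.
#' @examples
#' sequentialToAuthor(c(4, 5), missing = c(5, 6))  # 4 7
#' @export
sequentialToAuthor <- function(idx, missing) {
  idx <- as.integer(idx)
  missing <- sort(unique(as.integer(missing)))
  if (any(idx < 1L)) stop("sequential indices must be >= 1")
  hi <- max(idx, 0L) + length(missing)
  observed <- setdiff(seq_len(hi), missing)
  observed[idx]
}

#' @rdname sequentialToAuthor
#' @export
authorToSequential <- function(idx, missing) {
  idx <- as.integer(idx)
  missing <- sort(unique(as.integer(missing)))
  if (any(idx %in% missing))
    stop("author residue(s) ", paste(intersect(idx, missing), collapse = ", "),
         " are listed as missing")
  vapply(idx, function(i) i - sum(missing < i), integer(1))
}

#' Map reference residue numbers to alignment columns
#'
#' Residue \code{r} of the reference sequence maps to the alignment column
#' holding its \code{r}-th non-gap symbol. The map is strictly increasing
#' and covers 1..L with L the ungapped reference length.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param refId id of the reference sequence.
#' @return a \code{\linkS4class{ResidueMap}}.
#' @examples
#' a <- ProteinAlignment(c(ref = "A-CD", s2 = "ACCD"))
#' buildResidueMap(a, "ref")@columns  # 1 3 4
#' @export
buildResidueMap <- function(a, refId) {
  stopifnot(is(a, "ProteinAlignment"))
  if (!refId %in% seqIds(a)) stop("unknown reference id: ", refId)
  row <- a@seqs[refId, ]
  cols <- which(row != "-")
  if (!length(cols)) stop("reference row '", refId, "' is all gaps")
  new("ResidueMap", refId = refId, columns = as.integer(cols))
}

#' Alignment columns of a compartment
#'
#' Composes a residue map with a compartment: each compartment residue
#' number (author numbering, i.e. position in the ungapped reference)
#' selects one alignment column. Residue-name mismatches between the table
#' and the reference row produce warnings, not errors — crystal structures
#' and database sequences legitimately differ.
#'
#' @param map a \code{\linkS4class{ResidueMap}}.
#' @param comp a \code{\linkS4class{Compartment}}.
#' @param a optional \code{\linkS4class{ProteinAlignment}} for the
#'   residue-name cross-check.
#' @return integer vector of alignment columns (one per compartment
#'   residue, in table order).
#' @export
compartmentColumns <- function(map, comp, a = NULL) {
  stopifnot(is(map, "ResidueMap"), is(comp, "Compartment"))
  num <- comp@residues$number
  L <- length(map@columns)
  if (any(bad <- num < 1L | num > L))
    stop("compartment '", comp@name, "' residue number(s) beyond the ",
         "ungapped reference length ", L, ": ",
         paste(num[bad], collapse = ", "))
  cols <- map@columns[num]
  if (!is.null(a)) {
    sym <- a@seqs[map@refId, cols]
    want <- .toOneLetter(comp@residues$name)
    if (any(ok <- sym != want))
      warning("residue name mismatch at ", sum(ok), " position(s) of ",
              "compartment '", comp@name, "'")
  }
  cols
}
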