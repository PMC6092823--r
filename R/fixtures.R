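#' @include alignment-io.R
NULL

## run code under a private RNG stream without disturbing the caller's seed
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic protein alignment
#'
#' Seedable generator for test alignments with controlled structure. Each
#' column draws residues i.i.d. from a focal-residue mixture: with
#' conservation level \eqn{c}, the column's focal residue has probability
#' \eqn{c + (1 - c)/20} and every other residue \eqn{(1 - c)/20}; level 1
#' forces an invariant column, level 0 is uniform over the 20 residues.
#' Gap blocks emulate sequences carrying extra domains or large
#' insertions (a contiguous column range gapped in a fraction of the
#' sequences); duplicate clusters emulate taxonomic bias (exact copies of
#' a source row, optionally with a few point substitutions). Gap blocks
#' are applied after duplication, so duplicate rows hit by a gap block can
#' diverge from their source inside the block.
#'
#' @param nSeq number of sequences.
#' @param nCol number of columns.
#' @param conservation per-column conservation level in [0, 1]; scalar or
#'   length-\code{nCol} vector. Default 0.8.
#' @param gapBlocks list of \code{list(cols =, fraction =)} entries:
#'   column indices to gap and the fraction of sequences affected.
#' @param duplicates list of \code{list(source =, targets =, mutations =
#'   0)} entries: row indices \code{targets} become copies of row
#'   \code{source} with \code{mutations} random substitutions each.
#' @param seed integer seed; the generator is bit-reproducible given
#'   (arguments, seed) and leaves the caller's RNG state untouched.
#' @return a \code{\linkS4class{ProteinAlignment}} with ids
#'   \code{seq1..seqN}.
#' @examples
#' a <- generateMsa(10, 20, conservation = 0.9, seed = 1)
#' identical(alnStrings(a), alnStrings(generateMsa(10, 20,
#'           conservation = 0.9, seed = 1)))
#' @export
generateMsa <- function(nSeq, nCol, conservation = 0.8,
                        gapBlocks = list(), duplicates = list(),
                        seed = 1L) {
  stopifnot(nSeq >= 2, nCol >= 1)
  conservation <- rep_len(conservation, nCol)
  if (any(conservation < 0 | conservation > 1))
    stop("conservation levels must lie in [0, 1]")
  .withSeed(seed, {
    m <- matrix("", nSeq, nCol,
                dimnames = list(paste0("seq", seq_len(nSeq)), NULL))
    for (j in seq_len(nCol)) {
      focal <- sample(.AA20, 1L)
      pr <- rep((1 - conservation[j]) / 20, 20)
      names(pr) <- .AA20
      pr[focal] <- pr[focal] + conservation[j]
      m[, j] <- sample(.AA20, nSeq, replace = TRUE, prob = pr)
    }
    for (d in duplicates) {
      src <- m[d$source, ]
      for (t in d$targets) {
        row <- src
        nmut <- if (is.null(d$mutations)) 0L else d$mutations
        if (nmut > 0L) {
          pos <- sample(nCol, min(nmut, nCol))
          row[pos] <- vapply(row[pos], function(cur)
            sample(setdiff(.AA20, cur), 1L), character(1))
        }
        m[t, ] <- row
      }
    }
    for (b in gapBlocks) {
      if (any(b$cols < 1 | b$cols > nCol))
        stop("gap block columns out of range")
      if (b$fraction < 0 || b$fraction > 1)
        stop("gap block fraction must lie in [0, 1]")
      rows <- sample(nSeq, round(b$fraction * nSeq))
      m[rows, b$cols] <- "-"
    }
    new("ProteinAlignment", seqs = m, colMap = seq_len(nCol))
  })
}

#' Write an alignment to FASTA or Clustal
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param path output path.
#' @param format \code{"fasta"} or \code{"clustal"}.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(a, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  s <- alnStrings(a)
  if (format == "fasta") {
    writeLines(paste0(">", names(s), "\n", s, collapse = "\n"), path)
  } else {
    ids <- formatC(names(s), width = max(nchar(names(s))) + 4L,
                   flag = "-")
    out <- c("CLUSTAL multiple sequence alignment", "", "")
    start <- 1L
    while (start <= nCol(a)) {
      end <- min(start + 59L, nCol(a))
      out <- c(out, paste0(ids, substr(s, start, end)), "")
      start <- end + 1L
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Generate a consistent structure fixture
#'
#' Emits a toy protein-structure bundle for exercising the numbering
#' correction and residue mapping: a reference sequence of \code{nRes}
#' author-numbered residues, a minimal PDB fragment whose REMARK 465
#' section lists exactly the \code{missing} author residues for chain
#' \code{chain}, and a compartment table in sequential (observed)
#' numbering whose residue names match the reference sequence — so that
#' \code{\link{correctNumbering}} followed by
#' \code{\link{buildResidueMap}}/\code{\link{compartmentColumns}}
#' round-trips exactly.
#'
#' @param nRes number of author-numbered residues.
#' @param missing author residue numbers absent from the structure
#'   (subset of 1..nRes).
#' @param compartment sequential (observed) indices forming the
#'   compartment; must be <= nRes - length(missing).
#' @param chain chain id used in the PDB fragment.
#' @param dir output directory (created if needed); default a fresh
#'   temporary directory.
#' @param seed integer seed.
#' @return list with \code{refSeq} (author-length character string),
#'   \code{pdbFile}, \code{compartmentFile}, \code{authorNumbers} (the
#'   expected author numbering of the compartment), and \code{dir}.
#' @export
generateStructureFixture <- function(nRes, missing = integer(0),
                                     compartment = integer(0),
                                     chain = "A", dir = tempfile("fix"),
                                     seed = 1L) {
  missing <- sort(unique(as.integer(missing)))
  if (length(missing) && (any(missing < 1L) || any(missing > nRes)))
    stop("'missing' must be a subset of 1..nRes")
  nObs <- nRes - length(missing)
  compartment <- as.integer(compartment)
  if (length(compartment) && (any(compartment < 1L) ||
                              any(compartment > nObs)))
    stop("compartment indices must lie in 1..", nObs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .withSeed(seed, {
    refSeq <- sample(.AA20, nRes, replace = TRUE)
    feat <- round(stats::runif(length(compartment)), 3)

    authorNumbers <- sequentialToAuthor(compartment, missing)
    compFile <- file.path(dir, "compartment.tsv")
    writeLines(c("number\tname\tfeature",
                 sprintf("%d\t%s\t%.3f", compartment,
                         .AA3[refSeq[authorNumbers]], feat)),
               compFile)

    pdbFile <- file.path(dir, "structure.pdb")
    hdr <- c("HEADER    SYNTHETIC TEST STRUCTURE",
             "REMARK 465",
             "REMARK 465 MISSING RESIDUES",
             "REMARK 465 THE FOLLOWING RESIDUES WERE NOT LOCATED IN THE",
             "REMARK 465 EXPERIMENT.",
             "REMARK 465   M RES C SSSEQI")
    rec <- if (length(missing))
      sprintf("REMARK 465     %3s %s %5d", .AA3[refSeq[missing]], chain,
              missing) else character(0)
    writeLines(c(hdr, rec, "END"), pdbFile)

    list(refSeq = paste0(refSeq, collapse = ""),
         pdbFile = pdbFile, compartmentFile = compFile,
         authorNumbers = authorNumbers, dir = dir)
  })
}
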