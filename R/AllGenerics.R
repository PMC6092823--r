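#' @include AllClasses.R
NULL

#' Accessors for alignment objects
#'
#' \code{seqIds} returns the sequence identifiers, \code{nSeq} and
#' \code{nCol} the numbers of sequences and alignment columns,
#' \code{alnMatrix} the underlying character matrix, and \code{alnStrings}
#' the rows pasted back into strings.
#'
#' @param x a \code{\linkS4class{ProteinAlignment}}.
#' @return See the individual descriptions.
#' @examples
#' a <- ProteinAlignment(c(s1 = "AC-D", s2 = "ACAD"))
#' seqIds(a)
#' nCol(a)
#' @name alignment-accessors
#' @aliases seqIds nSeq nCol alnMatrix alnStrings
NULL

#' @rdname alignment-accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname alignment-accessors
#' @export
setGeneric("nSeq", function(x) standardGeneric("nSeq"))

#' @rdname alignment-accessors
#' @export
setGeneric("nCol", function(x) standardGeneric("nCol"))

#' @rdname alignment-accessors
#' @export
setGeneric("alnMatrix", function(x) standardGeneric("alnMatrix"))

#' @rdname alignment-accessors
#' @export
setGeneric("alnStrings", function(x) standardGeneric("alnStrings"))

#' @rdname alignment-accessors
setMethod("seqIds", "ProteinAlignment", function(x) rownames(x@seqs))

#' @rdname alignment-accessors
setMethod("nSeq", "ProteinAlignment", function(x) nrow(x@seqs))

#' @rdname alignment-accessors
setMethod("nCol", "ProteinAlignment", function(x) ncol(x@seqs))

#' @rdname alignment-accessors
setMethod("alnMatrix", "ProteinAlignment", function(x) x@seqs)

#' @rdname alignment-accessors
setMethod("alnStrings", "ProteinAlignment", function(x) {
  s <- apply(x@seqs, 1L, paste0, collapse = "")
  if (nCol(x) == 0L) s <- setNames(character(nSeq(x)), seqIds(x))
  s
})

#' Original column indices retained through trimming
#'
#' @param x a \code{\linkS4class{ProteinAlignment}}.
#' @return integer vector, one entry per current column, giving the index
#'   each column had in the alignment as originally read.
#' @export
setGeneric("columnProvenance", function(x) standardGeneric("columnProvenance"))

#' @rdname columnProvenance
setMethod("columnProvenance", "ProteinAlignment", function(x) x@colMap)

#' Score values and orientation of a conservation profile
#'
#' @param x a \code{\linkS4class{ConservationProfile}}.
#' @return \code{scoreValues}: numeric vector of per-column scores;
#'   \code{scoreOrientation}: \code{"variability"} or \code{"conservation"};
#'   \code{metricName}: the metric label.
#' @name profile-accessors
#' @aliases scoreValues scoreOrientation metricName
NULL

#' @rdname profile-accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname profile-accessors
#' @export
setGeneric("scoreOrientation", function(x) standardGeneric("scoreOrientation"))

#' @rdname profile-accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname profile-accessors
setMethod("scoreValues", "ConservationProfile", function(x) x@values)

#' @rdname profile-accessors
setMethod("scoreOrientation", "ConservationProfile", function(x) x@orientation)

#' @rdname profile-accessors
setMethod("metricName", "ConservationProfile", function(x) x@metric)

#' Consensus accessors
#'
#' @param x a \code{\linkS4class{ConsensusResult}}.
#' @return \code{consensusString}: the consensus as a single string;
#'   \code{consensusSymbols}: per-column character vector.
#' @name consensus-accessors
#' @aliases consensusString consensusSymbols
NULL

#' @rdname consensus-accessors
#' @export
setGeneric("consensusSymbols", function(x) standardGeneric("consensusSymbols"))

#' @rdname consensus-accessors
setMethod("consensusSymbols", "ConsensusResult", function(x) x@symbols)

#' Compartment accessors
#'
#' @param x a \code{\linkS4class{Compartment}}.
#' @return \code{compartmentName}: the name; \code{compartmentResidues}: the
#'   residue data.frame (columns \code{number}, \code{name}, features).
#' @name compartment-accessors
#' @aliases compartmentName compartmentResidues
NULL

#' @rdname compartment-accessors
#' @export
setGeneric("compartmentName", function(x) standardGeneric("compartmentName"))

#' @rdname compartment-accessors
#' @export
setGeneric("compartmentResidues",
           function(x) standardGeneric("compartmentResidues"))

#' @rdname compartment-accessors
setMethod("compartmentName", "Compartment", function(x) x@name)

#' @rdname compartment-accessors
setMethod("compartmentResidues", "Compartment", function(x) x@residues)

setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment: %d sequences x %d columns\n",
              nSeq(object), nCol(object)))
  ids <- seqIds(object)
  k <- min(5L, length(ids))
  for (i in seq_len(k)) {
    s <- alnStrings(object)[i]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 50), "...")
    cat(sprintf("  %-15s %s\n", ids[i], s))
  }
  if (length(ids) > k) cat(sprintf("  ... and %d more\n", length(ids) - k))
})

setMethod("show", "ConservationProfile", function(object) {
  v <- object@values
  cat(sprintf("ConservationProfile '%s' (%s): %d columns\n",
              object@metric, object@orientation, length(v)))
  cat(sprintf("  range [%.4g, %.4g], %d NaN column(s)\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

setMethod("show", "ConsensusResult", function(object) {
  s <- paste0(object@symbols, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 60), "...")
  cat(sprintf("ConsensusResult (threshold %.2f): %s\n", object@threshold, s))
})

setMethod("show", "Compartment", function(object) {
  feats <- setdiff(colnames(object@residues), c("number", "name"))
  cat(sprintf("Compartment '%s': %d residues, %d feature(s)%s\n",
              object@name, nrow(object@residues), length(feats),
              if (length(feats)) paste0(" [", paste(feats, collapse = ", "),
                                        "]") else ""))
})

setMethod("show", "ResidueMap", function(object) {
  cat(sprintf("ResidueMap for '%s': %d residues -> columns %s..%s\n",
              object@refId, length(object@columns),
              if (length(object@columns)) object@columns[1] else "-",
              if (length(object@columns))
                object@columns[length(object@columns)] else "-"))
})

setMethod("show", "GuideTree", function(object) {
  cat(sprintf("GuideTree (UPGMA): %d leaves, root height %.4g\n",
              length(object@labels), max(object@heights)))
})

setMethod("show", "KSResult", function(object) {
  cat(sprintf("KS two-sample test: D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              object@D, object@p, object@n1, object@n2))
})
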