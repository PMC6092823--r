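#' @import methods
NULL

#' The 20 standard amino acids, one-letter codes, alphabetical
#' @keywords internal
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
          G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
          M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
          S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR",
          X = "UNK")

#' Protein multiple sequence alignment
#'
#' Rectangular container for an aligned set of protein sequences. Rows are
#' sequences (with unique identifiers), columns are alignment positions.
#' Symbols are uppercase one-letter residue codes, the gap character
#' \code{"-"}, or \code{"X"} for unknown/non-standard residues. After
#' \code{\link{applyGrouping}} the residue alphabet may be an arbitrary set
#' of single-character group symbols; gaps and \code{"X"} keep their meaning.
#'
#' @slot seqs character matrix of single characters; rownames are the
#'   sequence identifiers.
#' @slot colMap integer vector of original column indices (provenance kept
#'   across \code{\link{trimAlignment}} calls).
#' @seealso \code{\link{readAlignment}}, \code{\link{trimAlignment}}
#' @export
setClass("ProteinAlignment",
         representation(seqs = "matrix", colMap = "integer"))

setValidity("ProteinAlignment", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("'seqs' must be a character matrix")
  if (is.null(rownames(m))) return("sequences must carry identifiers")
  if (anyDuplicated(rownames(m)))
    return(paste0("duplicate sequence id: ",
                  rownames(m)[duplicated(rownames(m))][1L]))
  if (ncol(m) > 0 && any(nchar(m) != 1L))
    return("alignment cells must be single characters")
  if (length(object@colMap) != ncol(m))
    return("colMap length must equal the number of columns")
  TRUE
})

#' Consensus sequence of an alignment
#'
#' @slot symbols character vector (length = number of columns) holding the
#'   winning residue per column, or \code{"X"} where no residue exceeds the
#'   threshold.
#' @slot threshold minimum frequency (over all rows, gaps included in the
#'   denominator) that the winning residue must strictly exceed.
#' @slot winFreq numeric vector of the winning residue frequency per column.
#' @slot tie logical vector; \code{TRUE} where the winner was picked
#'   alphabetically among tied residues.
#' @seealso \code{\link{consensusSequence}}
#' @export
setClass("ConsensusResult",
         representation(symbols = "character", threshold = "numeric",
                        winFreq = "numeric", tie = "logical"))

setValidity("ConsensusResult", function(object) {
  n <- length(object@symbols)
  if (length(object@winFreq) != n || length(object@tie) != n)
    return("symbols, winFreq and tie must have equal length")
  if (object@threshold <= 0 || object@threshold > 1)
    return("threshold must be in (0, 1]")
  TRUE
})

#' Per-column conservation/variability profile
#'
#' Holds one score per alignment column for a single named metric, together
#' with its orientation: \code{"variability"} means larger values flag more
#' variable columns, \code{"conservation"} the opposite. All-gap columns
#' carry \code{NaN}.
#'
#' @slot metric metric name, e.g. \code{"shannon"} or \code{"escore"}.
#' @slot values numeric vector, one value per column.
#' @slot orientation \code{"variability"} or \code{"conservation"}.
#' @seealso \code{\link{scoreConservation}}, \code{\link{scoreRET}},
#'   \code{\link{scoreCRE}}, \code{\link{scoreLandgraf}}
#' @export
setClass("ConservationProfile",
         representation(metric = "character", values = "numeric",
                        orientation = "character"))

setValidity("ConservationProfile", function(object) {
  if (!object@orientation %in% c("variability", "conservation"))
    return("orientation must be 'variability' or 'conservation'")
  TRUE
})

#' Functional compartment of a protein structure
#'
#' A named set of structure residues (e.g. the lining of a tunnel, a binding
#' site) that is dispersed in primary sequence but adjacent in the tertiary
#' structure, with optional numeric features per residue (B-factors, RMSF,
#' solvent accessibility, ...).
#'
#' @slot name compartment name.
#' @slot residues data.frame with columns \code{number} (integer, unique),
#'   \code{name} (residue code, 1- or 3-letter) and zero or more numeric
#'   feature columns.
#' @seealso \code{\link{readCompartmentTable}}, \code{\link{correctNumbering}}
#' @export
setClass("Compartment",
         representation(name = "character", residues = "data.frame"))

setValidity("Compartment", function(object) {
  df <- object@residues
  if (!all(c("number", "name") %in% colnames(df)))
    return("residue table needs 'number' and 'name' columns")
  if (anyDuplicated(df$number))
    return(paste0("duplicate residue number: ",
                  df$number[duplicated(df$number)][1L]))
  TRUE
})

#' Map from reference residue numbers to alignment columns
#'
#' @slot refId identifier of the reference sequence in the alignment.
#' @slot columns integer vector; entry \code{r} is the alignment column
#'   holding the \code{r}-th non-gap symbol of the reference row. Strictly
#'   increasing.
#' @seealso \code{\link{buildResidueMap}}, \code{\link{compartmentColumns}}
#' @export
setClass("ResidueMap",
         representation(refId = "character", columns = "integer"))

setValidity("ResidueMap", function(object) {
  if (length(object@columns) && any(diff(object@columns) <= 0L))
    return("mapped columns must be strictly increasing")
  TRUE
})

#' Rooted ultrametric guide tree (UPGMA)
#'
#' Agglomeration history in \code{\link[stats]{hclust}} layout: row \code{i}
#' of \code{merge} records the i-th fusion (negative entries index leaves,
#' positive entries earlier fusions); \code{heights} stores the UPGMA node
#' height of each fusion, i.e. half the distance at which the two clusters
#' merged. Merge order is deterministic: ties are broken towards the pair
#' containing the lexicographically smallest leaf label.
#'
#' @slot merge integer matrix (n-1 x 2), hclust convention.
#' @slot heights numeric vector of node heights (half merge distances),
#'   nondecreasing.
#' @slot labels leaf labels (sequence ids).
#' @seealso \code{\link{upgmaTree}}, \code{\link{scoreRET}}
#' @export
setClass("GuideTree",
         representation(merge = "matrix", heights = "numeric",
                        labels = "character"))

setValidity("GuideTree", function(object) {
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L || length(object@heights) != n - 1L)
    return("a tree over n leaves has n-1 internal nodes")
  if (is.unsorted(object@heights + 1e-12))
    return("node heights must be nondecreasing towards the root")
  TRUE
})

#' Two-sample Kolmogorov-Smirnov comparison result
#'
#' @slot D sup-distance between the two empirical CDFs, in [0, 1].
#' @slot p asymptotic p-value.
#' @slot n1,n2 sample sizes (compartment, rest).
#' @seealso \code{\link{ksCompare}}
#' @export
setClass("KSResult",
         representation(D = "numeric", p = "numeric",
                        n1 = "integer", n2 = "integer"))

setValidity("KSResult", function(object) {
  if (object@D < 0 || object@D > 1) return("D must lie in [0, 1]")
  if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
  TRUE
})
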