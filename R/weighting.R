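#' @include profile.R
NULL

#' Henikoff & Henikoff position-based sequence weights
#'
#' Down-weights redundant sequences so that taxonomically biased alignments
#' (many near-duplicates of one lineage) do not dominate column statistics.
#' The raw weight of sequence \eqn{s} is \eqn{\sum_c 1 / (k_c \, n_{c,x})}
#' over columns \eqn{c}, where \eqn{k_c} is the number of distinct symbols
#' in the column (the gap counts as a symbol type) and \eqn{n_{c,x}} the
#' count of the sequence's own symbol \eqn{x} there. Weights are normalized
#' to sum to 1.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}} with at least 2 rows.
#' @return named numeric vector of weights summing to 1.
#' @references Henikoff S, Henikoff JG (1994) Position-based sequence
#'   weights. J Mol Biol 243:574-578.
#' @examples
#' a <- ProteinAlignment(c(s1 = "AAA", s2 = "AAA", s3 = "AAC"))
#' round(henikoffWeights(a), 4)  # 0.3056 0.3056 0.3889
#' @export
henikoffWeights <- function(a) {
  stopifnot(is(a, "ProteinAlignment"))
  if (nSeq(a) < 2L) stop("at least 2 sequences required")
  m <- a@seqs
  raw <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    cnt <- table(m[, j])
    k <- length(cnt)
    raw <- raw + 1 / (k * as.numeric(cnt[m[, j]]))
  }
  w <- raw / sum(raw)
  names(w) <- seqIds(a)
  w
}

#' Background conditional probabilities from the BLOSUM62 matrix
#'
#' Builds the 20 x 20 matrix of conditionals \eqn{g(a \mid b)} used by the
#' substitution-based pseudo-count scheme. Target (joint) frequencies are
#' recovered from the half-bit BLOSUM62 scores \eqn{S} as
#' \eqn{q_{ab} \propto p_a p_b 2^{S_{ab}/2}} with the Robinson & Robinson
#' amino-acid background \eqn{p}, then each column is normalized:
#' \eqn{g(a \mid b) = q_{ab} / \sum_a q_{ab}}. Rows index \eqn{a}, columns
#' index the conditioning residue \eqn{b}; every column sums to 1.
#'
#' @return 20 x 20 numeric matrix with dimnames over the amino acids.
#' @references Henikoff S, Henikoff JG (1996) Using substitution
#'   probabilities to improve position-specific scoring matrices. CABIOS
#'   12:135-143.
#' @export
blosumBackground <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62[.AA20, .AA20]
  ## Robinson & Robinson (1991) amino-acid frequencies
  p <- c(A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
         G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
         M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
         S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)
  p <- p[.AA20]
  q <- outer(p, p) * 2^(S / 2)
  sweep(q, 2L, colSums(q), "/")
}

#' Pseudo-count adjusted residue frequencies
#'
#' Stabilizes column frequency estimates for alignments with few sequences
#' by adding substitution-derived pseudo-counts. For residue \eqn{a} the
#' pseudo-count is \eqn{b_a = B \sum_b f_b \, g(a \mid b)} with \eqn{f} the
#' observed residue frequencies and \eqn{g} the background conditionals;
#' the adjusted frequency is \eqn{p'_a = (n_a + b_a) / (N + B)}. With
#' \eqn{B = 0} the observed frequencies are returned unchanged; with
#' \eqn{B > 0} every residue in the alphabet gets strictly positive mass.
#' Gap counts never receive pseudo-counts: the pseudo-mass is spread over
#' the residue alphabet only.
#'
#' @param counts named nonnegative numeric vector of residue counts (no gap
#'   entry; pass residue counts only).
#' @param B total pseudo-count mass; default \code{5 * k} with \code{k} the
#'   number of distinct residues observed.
#' @param background square conditional-probability matrix whose dimnames
#'   cover \code{names(counts)}; columns sum to 1. Default
#'   \code{\link{blosumBackground}()}.
#' @param extraMass additional non-residue mass (gap/'X' counts) to include
#'   in the denominator \eqn{N}; default 0.
#' @return named numeric frequency vector over \code{names(counts)}.
#' @examples
#' bg <- matrix(0.5, 2, 2, dimnames = list(c("A", "C"), c("A", "C")))
#' pseudocountFrequencies(c(A = 3, C = 1), B = 4, background = bg)["A"]
#' @export
pseudocountFrequencies <- function(counts, B = NULL,
                                   background = blosumBackground(),
                                   extraMass = 0) {
  if (is.null(names(counts))) stop("'counts' must be named by residue")
  if (any(counts < 0)) stop("counts must be nonnegative")
  k <- sum(counts > 0)
  if (is.null(B)) B <- 5 * k
  if (B < 0) stop("pseudo-count mass B must be nonnegative")
  alpha <- names(counts)
  if (length(bad <- setdiff(alpha, rownames(background))))
    stop("background matrix lacks residue(s): ", paste(bad, collapse = ", "))
  N <- sum(counts) + extraMass
  if (B == 0) return(counts / N)
  f <- if (sum(counts) > 0) counts / sum(counts) else
    setNames(rep(0, length(counts)), alpha)
  g <- background[alpha, alpha, drop = FALSE]
  b <- B * as.numeric(g %*% f)
  names(b) <- alpha
  (counts + b) / (N + B)
}

## adjust a residue-count matrix (rows = residues + '-','X') column-wise;
## returns adjusted frequency matrix for the chosen denominator:
## 'all'  -> gaps/'X' kept in the denominator (E_score's p)
## 'aa'   -> residues only (entropy scores' q)
.pcFreqMatrix <- function(cnt, alphabet, B, background, denominator) {
  aa <- cnt[alphabet, , drop = FALSE]
  other <- colSums(cnt) - colSums(aa)
  out <- matrix(NA_real_, nrow = length(alphabet), ncol = ncol(cnt),
                dimnames = list(alphabet, NULL))
  for (j in seq_len(ncol(cnt))) {
    if (sum(aa[, j]) == 0) next
    extra <- if (denominator == "all") other[j] else 0
    out[, j] <- pseudocountFrequencies(aa[, j], B = B,
                                       background = background,
                                       extraMass = extra)
  }
  out
}
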