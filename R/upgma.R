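#' @include consensus.R
NULL

#' UPGMA guide tree from a distance matrix
#'
#' Standard unweighted pair-group agglomeration with arithmetic-mean
#' linkage (implemented via the exact Lance-Williams update). The height of
#' each internal node is half the distance at which its two clusters merge,
#' so leaf-to-root path lengths are equal (ultrametric). When several pairs
#' are tied at the minimum distance, the pair whose members contain the
#' lexicographically smallest leaf label merges first, making the tree
#' deterministic.
#'
#' @param d square symmetric numeric matrix with zero diagonal and
#'   dimnames, e.g. from \code{\link{pairwiseDistances}}.
#' @return a \code{\linkS4class{GuideTree}}.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgmaTree(d)
#' @export
upgmaTree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("'d' must be a square matrix")
  n <- nrow(d)
  if (n < 2L) stop("at least 2 sequences required")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("s", 1:n)
  if (max(abs(d - t(d))) > 1e-9) stop("'d' must be symmetric")
  labels <- rownames(d)

  D <- d
  active <- seq_len(n)              # indices into bookkeeping vectors
  code <- -seq_len(n)               # hclust convention
  size <- rep(1L, n)
  rep_ <- labels                    # lexicographically smallest member label
  merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    ## minimum off-diagonal distance among active clusters
    best <- NULL
    bestKey <- NULL
    dmin <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in seq(ii + 1L, length(active))) {
        i <- active[ii]; j <- active[jj]
        dij <- D[i, j]
        if (dij < dmin - 1e-12) {
          dmin <- dij; best <- c(i, j); bestKey <- sort(c(rep_[i], rep_[j]))
        } else if (dij <= dmin + 1e-12) {
          key <- sort(c(rep_[i], rep_[j]))
          if (key[1L] < bestKey[1L] ||
              (key[1L] == bestKey[1L] && key[2L] < bestKey[2L])) {
            dmin <- min(dmin, dij); best <- c(i, j); bestKey <- key
          }
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(code[i], code[j]))
    heights[step] <- dmin / 2
    ## Lance-Williams UPGMA update, new cluster stored in slot i
    others <- setdiff(active, c(i, j))
    D[i, others] <- D[others, i] <-
      (size[i] * D[i, others] + size[j] * D[j, others]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    code[i] <- step
    rep_[i] <- min(rep_[i], rep_[j])
    active <- setdiff(active, j)
  }
  heights <- cummax(heights)   # guard against 1e-16 float dips
  new("GuideTree", merge = merge, heights = heights, labels = labels)
}

#' Partition tree leaves into k groups
#'
#' Cuts the guide tree just below its \code{k - 1} highest internal nodes
#' (equivalently: replays all but the last \code{k - 1} merges), yielding
#' the \code{k} subtrees used by the Real-valued Evolutionary Trace. Height
#' ties follow the tree's deterministic merge order.
#'
#' @param tree a \code{\linkS4class{GuideTree}}.
#' @param k number of groups, 1..n_leaves.
#' @return named integer vector assigning each leaf label a group in
#'   \code{1..k}.
#' @export
treePartition <- function(tree, k) {
  stopifnot(is(tree, "GuideTree"))
  n <- length(tree@labels)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  grp <- -seq_len(n)                # start: leaf i in pseudo-group -i
  nm <- n - k                       # merges to replay
  for (m in seq_len(nm)) {
    a <- tree@merge[m, 1L]; b <- tree@merge[m, 2L]
    grp[grp %in% c(a, b)] <- m
  }
  setNames(as.integer(factor(grp, levels = unique(grp))), tree@labels)
}

## gap-excluded Shannon entropy of each column over a subset of rows
.groupColumnEntropies <- function(m, rows, alphabet) {
  sub <- m[rows, , drop = FALSE]
  cnt <- matrix(0, nrow = length(alphabet), ncol = ncol(m))
  for (s in seq_along(alphabet)) {
    hit <- sub == alphabet[s]
    cnt[s, ] <- if (nrow(sub) == 1L) as.numeric(hit) else colSums(hit)
  }
  tot <- colSums(cnt)
  H <- numeric(ncol(m))
  nz <- tot > 0
  if (any(nz)) {
    q <- sweep(cnt[, nz, drop = FALSE], 2L, tot[nz], "/")
    lq <- ifelse(q > 0, q * log(q), 0)
    H[nz] <- -colSums(lq)
  }
  H
}

#' Real-valued Evolutionary Trace
#'
#' Cumulates within-group column entropies over successive partitions of
#' the UPGMA guide tree: for an alignment of \eqn{N} sequences,
#' \deqn{\rho_i = 1 + \sum_{n=1}^{N-1} \frac{1}{n} \sum_{g=1}^{n} H_{i,g},}
#' where the \eqn{n} groups are the subtrees left after removing the
#' \eqn{n - 1} highest internal nodes and \eqn{H_{i,g}} is the gap-excluded
#' Shannon entropy of column \eqn{i} within group \eqn{g}. Sequence
#' weighting is implicit in the tree: related sequences end up in the same
#' subtree and stop contributing once the partition separates lineages.
#' \eqn{\rho \ge 1}, with equality iff every group at every level is
#' invariant at the column; variability orientation.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param tree optional \code{\linkS4class{GuideTree}} over exactly the
#'   alignment's ids; default
#'   \code{upgmaTree(pairwiseDistances(a))}.
#' @return a \code{\linkS4class{ConservationProfile}} (metric
#'   \code{"ret"}).
#' @references Mihalek I, Res I, Lichtarge O (2004) A family of
#'   evolution-entropy hybrid methods for ranking protein residues by
#'   importance. J Mol Biol 336:1265-1282.
#' @export
scoreRET <- function(a, tree = NULL) {
  stopifnot(is(a, "ProteinAlignment"))
  if (nSeq(a) < 2L) stop("at least 2 sequences required")
  if (is.null(tree)) tree <- upgmaTree(pairwiseDistances(a))
  if (!setequal(tree@labels, seqIds(a)))
    stop("tree leaves do not match alignment ids")
  N <- nSeq(a)
  m <- a@seqs
  alpha <- .residueAlphabet(a)
  rho <- rep(1, nCol(a))
  idOrder <- seqIds(a)
  for (n in seq_len(N - 1L)) {
    part <- treePartition(tree, n)[idOrder]
    lvl <- numeric(nCol(a))
    for (g in unique(part)) {
      rows <- which(part == g)
      lvl <- lvl + .groupColumnEntropies(m, rows, alpha)
    }
    rho <- rho + lvl / n
  }
  allGap <- colSums(m != "-" & m != "X") == 0
  rho[allGap] <- NaN
  new("ConservationProfile", metric = "ret", values = rho,
      orientation = "variability")
}

#' Cumulative relative entropy across sequence subgroups
#'
#' Weighted Kullback-Leibler divergence of each subgroup's column
#' distribution from the pooled distribution:
#' \deqn{CRE_i = \sum_g \frac{N_g}{N} \sum_a p_{a,g}
#'   \ln\frac{p_{a,g}}{q_a},}
#' with \eqn{p_{\cdot,g}} the group's gap-excluded residue frequencies at
#' column \eqn{i} and \eqn{q} the pooled gap-excluded frequencies.
#' Zero-frequency terms contribute 0; a group with no residue at a column
#' is skipped there (with a warning). \eqn{CRE \ge 0}, equal to 0 iff all
#' group distributions match the pooled one. The default grouping cuts the
#' UPGMA guide tree at half its root height, so subgroups reflect the
#' pairwise-distance structure of the data.
#'
#' @param a a \code{\linkS4class{ProteinAlignment}}.
#' @param groups optional named vector/factor over the sequence ids (at
#'   least 2 distinct groups), or a list of id vectors partitioning the
#'   ids.
#' @return a \code{\linkS4class{ConservationProfile}} (metric
#'   \code{"cre"}).
#' @export
scoreCRE <- function(a, groups = NULL) {
  stopifnot(is(a, "ProteinAlignment"))
  if (nSeq(a) < 2L) stop("at least 2 sequences required")
  ids <- seqIds(a)
  if (is.null(groups)) {
    tree <- upgmaTree(pairwiseDistances(a))
    H <- max(tree@heights)
    k <- sum(tree@heights > H / 2) + 1L   # remove merges above half height
    if (k < 2L) k <- 2L
    groups <- treePartition(tree, k)
  }
  if (is.list(groups)) {
    gg <- rep(seq_along(groups), lengths(groups))
    names(gg) <- unlist(groups)
    groups <- gg
  }
  if (is.null(names(groups)) || !setequal(names(groups), ids))
    stop("groups must be named by, and partition, the sequence ids")
  groups <- groups[ids]
  if (length(unique(groups)) < 2L) stop("at least 2 groups required")
  m <- a@seqs
  alpha <- .residueAlphabet(a)
  N <- nSeq(a)
  isRes <- !(m %in% c("-", "X"))
  dim(isRes) <- dim(m)

  colFreq <- function(rows) {
    cnt <- matrix(0, length(alpha), ncol(m))
    sub <- m[rows, , drop = FALSE]
    for (s in seq_along(alpha)) {
      hit <- sub == alpha[s]
      cnt[s, ] <- if (length(rows) == 1L) as.numeric(hit) else colSums(hit)
    }
    cnt
  }
  pooled <- colFreq(seq_len(N))
  totQ <- colSums(pooled)
  q <- sweep(pooled, 2L, ifelse(totQ > 0, totQ, 1), "/")
  cre <- numeric(ncol(m))
  skipped <- FALSE
  for (g in unique(groups)) {
    rows <- which(groups == g)
    cnt <- colFreq(rows)
    totg <- colSums(cnt)
    empty <- totg == 0
    if (any(empty & totQ > 0)) skipped <- TRUE
    p <- sweep(cnt, 2L, ifelse(totg > 0, totg, 1), "/")
    term <- ifelse(p > 0 & q > 0, p * log(p / q), 0)
    contrib <- colSums(term) * (length(rows) / N)
    contrib[empty] <- 0
    cre <- cre + contrib
  }
  if (skipped)
    warning("group(s) with no residues at some column were skipped there")
  cre[totQ == 0] <- NaN
  new("ConservationProfile", metric = "cre", values = cre,
      orientation = "variability")
}
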