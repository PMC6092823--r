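# Shared fixtures and independent oracles used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

aln <- function(...) ProteinAlignment(c(...))

# Alignment whose columns are the given strings (one string per column).
alnFromColumns <- function(...) {
  cols <- strsplit(c(...), "", fixed = TRUE)
  m <- do.call(cbind, cols)
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  ProteinAlignment(m, normalize = FALSE)
}

# Brute-force Shannon entropy (nats) of a column's residue symbols,
# gaps/'X' excluded, written independently of the package internals.
bruteShannon <- function(symbols) {
  r <- symbols[!symbols %in% c("-", "X")]
  if (!length(r)) return(NaN)
  p <- as.numeric(table(r)) / length(r)
  -sum(p * log(p))
}

# Brute-force two-sample KS statistic: sup of |ECDF1 - ECDF2| evaluated
# at every sample point.
bruteKS <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  F1 <- vapply(pts, function(t) mean(x <= t), numeric(1))
  F2 <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(F1 - F2))
}

# Independent UPGMA oracle: cluster distances recomputed at every step as
# the arithmetic mean over the ORIGINAL distance matrix (no Lance-Williams
# update), same lexicographic tie-break. Returns a canonical nested-string
# signature with node heights, for comparison against treeSignature().
upgmaOracleSignature <- function(d, digits = 9) {
  labels <- rownames(d)
  clusters <- lapply(seq_along(labels), function(i) i)
  sigs <- labels
  reps <- labels
  while (length(clusters) > 1L) {
    best <- NULL; bestKey <- NULL; dmin <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq(i + 1L, length(clusters))) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(reps[i], reps[j]))
        if (dij < dmin - 1e-12 ||
            (dij <= dmin + 1e-12 &&
             (key[1] < bestKey[1] ||
              (key[1] == bestKey[1] && key[2] < bestKey[2])))) {
          dmin <- dij; best <- c(i, j); bestKey <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    kids <- sort(c(sigs[i], sigs[j]))
    sigs[i] <- sprintf("(%s,%s):%.*f", kids[1], kids[2], digits, dmin / 2)
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    reps[i] <- min(reps[i], reps[j])
    sigs <- sigs[-j]; clusters <- clusters[-j]; reps <- reps[-j]
  }
  sigs
}

# Canonical signature of a GuideTree, same format as the oracle's.
treeSignature <- function(tree, digits = 9) {
  sig <- character(nrow(tree@merge))
  leafSig <- tree@labels
  node <- function(code) if (code < 0) leafSig[-code] else sig[code]
  for (m in seq_len(nrow(tree@merge))) {
    kids <- sort(c(node(tree@merge[m, 1]), node(tree@merge[m, 2])))
    sig[m] <- sprintf("(%s,%s):%.*f", kids[1], kids[2], digits,
                      tree@heights[m])
  }
  sig[length(sig)]
}

# Reduced alphabet used in grouping-mode tests: hydrophobic / polar /
# negative / positive.
testGroupingScheme <- function() {
  g <- setNames(rep("p", 20), AA20)
  g[c("A", "V", "L", "I", "M", "F", "W", "C")] <- "h"
  g[c("D", "E")] <- "n"
  g[c("K", "R", "H")] <- "+"
  g
}

# Random symmetric distance matrix with zero diagonal.
randomDistanceMatrix <- function(n) {
  d <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  d[upper.tri(d)] <- round(runif(n * (n - 1) / 2, 0.05, 1), 3)
  d + t(d)
}
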