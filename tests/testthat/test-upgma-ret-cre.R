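test_that("UPGMA reproduces the hand-worked three-leaf tree", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t <- upgmaTree(d)
  expect_equal(t@heights, c(1, 2))
  expect_identical(treeSignature(t, 1), "((A,B):1.0,C):2.0")
})

test_that("equal distances collapse deterministically by lexicographic ids", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t <- upgmaTree(d)
  expect_equal(t@heights, rep(0.5, 3))
  # a merges first with b, then the (a,b) cluster absorbs c, then d
  expect_identical(treeSignature(t, 1),
                   "(((a,b):0.5,c):0.5,d):0.5")
})

test_that("UPGMA matches the exhaustive-merge oracle for n <= 6", {
  set.seed(100)
  for (trial in 1:100) {
    n <- sample(3:6, 1)
    d <- randomDistanceMatrix(n)
    t <- upgmaTree(d)
    expect_identical(treeSignature(t), upgmaOracleSignature(d))
    expect_false(is.unsorted(t@heights))       # ultrametric: monotone merges
    # and agrees with average-linkage hclust heights (as a set)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(t@heights), sort(hc$height / 2), tolerance = 1e-9)
  }
})

test_that("tree partitions cut just below the highest nodes", {
  d <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 4,
                8, 8, 4, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  t <- upgmaTree(d)
  p2 <- treePartition(t, 2)
  expect_equal(unname(p2), c(1, 1, 2, 2))
  p3 <- treePartition(t, 3)
  expect_equal(length(unique(p3)), 3L)
  # the (c,d) node is the second highest, so it is removed at k = 3
  expect_equal(unname(p3["a"]), unname(p3["b"]))
  expect_true(p3["c"] != p3["d"])
  expect_error(treePartition(t, 5), "k must be")
})

test_that("RET is 1 on identical sequences and 1 + ln 2 on two pairs", {
  ident <- aln(s1 = "ACDE", s2 = "ACDE", s3 = "ACDE", s4 = "ACDE")
  expect_equal(scoreValues(scoreRET(ident)), rep(1, 4))

  pairs <- aln(s1 = "AAAC", s2 = "AAAC", s3 = "CCAC", s4 = "CCAC")
  r <- scoreValues(scoreRET(pairs))
  expect_equal(r[1:2], rep(1 + log(2), 2))   # split resolves the AB|CC split
  expect_equal(r[3:4], rep(1, 2))
})

test_that("RET never drops below 1 and grows under within-group substitutions", {
  for (seed in 1:15) {
    a <- generateMsa(6, 10, conservation = runif(10), seed = seed)
    r <- scoreValues(scoreRET(a))
    expect_true(all(r >= 1 - 1e-12))
  }
  # substituting inside an otherwise invariant cluster cannot decrease rho
  base <- aln(s1 = "AAAA", s2 = "AAAA", s3 = "CCCC", s4 = "CCCC")
  tr <- upgmaTree(pairwiseDistances(base))
  mutated <- aln(s1 = "AAAA", s2 = "AADA", s3 = "CCCC", s4 = "CCCC")
  r0 <- scoreValues(scoreRET(base, tr))
  r1 <- scoreValues(scoreRET(mutated, tr))
  expect_true(all(r1 >= r0 - 1e-12))
  expect_gt(r1[3], r0[3])
})

test_that("RET errors on a tree whose leaves mismatch the alignment", {
  a <- aln(s1 = "AC", s2 = "AD", s3 = "CD")
  d <- randomDistanceMatrix(3)   # leaves a, b, c
  expect_error(scoreRET(a, upgmaTree(d)), "leaves")
})

test_that("CRE is zero for identical group distributions and ln 2 on AACC", {
  ident <- aln(s1 = "ACD", s2 = "ACD", s3 = "ACD", s4 = "ACD")
  expect_equal(scoreValues(scoreCRE(ident, c(s1 = 1, s2 = 1,
                                             s3 = 2, s4 = 2))),
               rep(0, 3))
  mirrored <- aln(s1 = "AC", s2 = "CA", s3 = "AC", s4 = "CA")
  expect_equal(scoreValues(scoreCRE(mirrored, c(s1 = 1, s2 = 1,
                                                s3 = 2, s4 = 2))),
               rep(0, 2))
  a <- alnFromColumns("AACC")
  expect_equal(scoreValues(scoreCRE(a, c(s1 = 1, s2 = 1, s3 = 2, s4 = 2))),
               log(2))
})

test_that("CRE is nonnegative and defaults to the half-height tree cut", {
  for (seed in 1:15) {
    a <- generateMsa(6, 12, conservation = runif(12), seed = seed)
    v <- scoreValues(scoreCRE(a))
    expect_true(all(v >= -1e-12))
  }
  a <- aln(s1 = "AAAA", s2 = "AAAA", s3 = "CCCC", s4 = "CCCC")
  expect_equal(scoreValues(scoreCRE(a)), rep(log(2), 4))
  expect_error(scoreCRE(a, groups = c(s1 = 1, s2 = 1, s3 = 1, s4 = 1)),
               "2 groups")
})

test_that("groups empty at a column are skipped with a warning", {
  a <- aln(s1 = "A-", s2 = "A-", s3 = "AC", s4 = "AC")
  expect_warning(v <- scoreValues(scoreCRE(a, c(s1 = 1, s2 = 1,
                                                s3 = 2, s4 = 2))),
                 "skipped")
  expect_equal(v[1], 0)
  expect_true(is.finite(v[2]))
})
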