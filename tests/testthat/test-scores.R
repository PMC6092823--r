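test_that("column profiles expose both frequency conventions", {
  cp <- columnProfile(aln(s1 = "A", s2 = "A", s3 = "A", s4 = "-"), 1)
  expect_equal(unname(cp@p["A"]), 0.75)  # gaps stay in the denominator
  expect_equal(cp@nTypes, 1L)
  expect_equal(cp@nAA, 3)

  cp2 <- columnProfile(alnFromColumns("AACC"), 1)
  expect_equal(max(cp2@p), 0.5)
  expect_equal(cp2@nTypes, 2L)

  allGap <- suppressWarnings(columnProfile(alnFromColumns("--"), 1))
  expect_equal(allGap@nTypes, 0L)
  expect_error(columnProfile(alnFromColumns("AC"), 3), "out of range")
})

test_that("E-score reproduces the three-equation worked fixture", {
  a <- alnFromColumns("AAAA", "AAA-", "AACC")
  e <- scoreValues(scoreConservation(a, "escore"))
  # P = (1, 0.75, 0.25); -ln P_norm = (0, 0.2877, 1.3863)
  expect_equal(round(e, 4), c(0, 0.2075, 1))
  expect_identical(scoreOrientation(scoreConservation(a, "escore")),
                   "variability")
})

test_that("E-score is bounded, zero on invariant gapless columns, attains 1", {
  for (seed in 1:200) {
    a <- generateMsa(8, 12, conservation = runif(12), seed = seed)
    m <- alnMatrix(a)
    m[, 1] <- "A"                       # invariant gapless column
    m[, 2] <- c("C", rep("A", 7))       # guaranteed variable column
    b <- ProteinAlignment(m, normalize = FALSE)
    e <- scoreValues(scoreConservation(b, "escore"))
    expect_true(all(e >= 0 & e <= 1))
    expect_identical(e[1], 0)
    expect_true(any(e == 1))
  }
})

test_that("Shannon matches the brute-force oracle to 1e-12", {
  for (seed in 1:50) {
    a <- generateMsa(9, 10, conservation = runif(10), seed = seed,
                     gapBlocks = list(list(cols = 1:3, fraction = 0.4)))
    h <- scoreValues(scoreConservation(a, "shannon"))
    ref <- apply(alnMatrix(a), 2, bruteShannon)
    expect_equal(h, unname(ref), tolerance = 1e-12)
  }
})

test_that("Schneider is the ln-20 normalization and hits 1 on 20 types", {
  a20 <- alnFromColumns(paste0(AA20, collapse = ""))
  expect_equal(scoreValues(scoreConservation(a20, "schneider")), 1)
  for (seed in 1:20) {
    a <- generateMsa(6, 8, conservation = runif(8), seed = seed)
    s <- scoreValues(scoreConservation(a, "schneider"))
    h <- scoreValues(scoreConservation(a, "shannon"))
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(s, h / log(20), tolerance = 1e-12)
  }
})

test_that("Kabat equals k N / n1 and is 1 exactly on invariant columns", {
  expect_equal(scoreValues(scoreConservation(alnFromColumns("AACC"),
                                             "kabat")), 4)
  # invariant over non-gap rows, with gaps present
  expect_equal(scoreValues(scoreConservation(alnFromColumns("AAA-"),
                                             "kabat")), 1)
  for (seed in 1:20) {
    a <- generateMsa(7, 10, conservation = runif(10), seed = seed)
    v <- scoreValues(scoreConservation(a, "kabat"))
    m <- alnMatrix(a)
    invariant <- apply(m, 2, function(col) {
      r <- col[!col %in% c("-", "X")]
      length(unique(r)) == 1
    })
    expect_true(all(v >= 1 - 1e-12))
    expect_equal(v == 1, unname(invariant))
  }
})

test_that("an invariant gapless column is maximally conserved everywhere", {
  a <- alnFromColumns("AAAA", "ACCD")
  expect_equal(scoreValues(scoreConservation(a, "shannon"))[1], 0)
  expect_equal(scoreValues(scoreConservation(a, "schneider"))[1], 0)
  expect_equal(scoreValues(scoreConservation(a, "kabat"))[1], 1)
  expect_equal(scoreValues(scoreConservation(a, "escore"))[1], 0)
})

test_that("all-gap columns yield NaN with a warning and are excluded from maxima", {
  a <- alnFromColumns("AAAA", "----", "AACC")
  for (mt in c("shannon", "schneider", "kabat", "escore")) {
    expect_warning(v <- scoreValues(scoreConservation(a, mt)), "all-gap")
    expect_true(is.nan(v[2]))
  }
  e <- suppressWarnings(scoreValues(scoreConservation(a, "escore")))
  expect_equal(e[c(1, 3)], c(0, 1))
})

test_that("scores are invariant under row permutation (weights permuted)", {
  a <- generateMsa(6, 15, conservation = 0.5, seed = 5)
  w <- henikoffWeights(a)
  perm <- c(3, 6, 1, 5, 2, 4)
  b <- ProteinAlignment(alnMatrix(a)[perm, ], normalize = FALSE)
  for (mt in c("shannon", "kabat", "escore")) {
    expect_equal(scoreValues(scoreConservation(b, mt, weights = w[perm])),
                 scoreValues(scoreConservation(a, mt, weights = w)),
                 tolerance = 1e-12)
  }
})

test_that("weighted scoring replaces counts with weight sums", {
  # weights collapsing two duplicate rows onto one effective sequence
  a <- aln(s1 = "AC", s2 = "AC", s3 = "CC")
  w <- c(0.25, 0.25, 0.5)
  h <- scoreValues(scoreConservation(a, "shannon", weights = w))
  expect_equal(h[1], log(2))      # effective 50/50 A/C
  expect_equal(h[2], 0)
})

test_that("pseudo-counts shift scores smoothly and keep bounds", {
  a <- generateMsa(5, 10, conservation = 0.6, seed = 9)
  for (mt in c("shannon", "schneider", "kabat", "escore")) {
    raw <- scoreValues(scoreConservation(a, mt))
    pc <- scoreValues(scoreConservation(a, mt, pseudocounts = TRUE))
    expect_true(all(is.finite(pc)))
    if (mt == "escore") expect_true(all(pc >= 0 & pc <= 1))
    if (mt == "shannon") expect_true(all(pc >= raw - 1e-9))  # smoothing
  }
})

test_that("Landgraf reproduces the toy fixture and orders substitutions", {
  S <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(S) <- 4
  S["A", "B"] <- S["B", "A"] <- 2   # B closer to A than C is
  a <- alnFromColumns("AACC")
  expect_equal(scoreValues(scoreLandgraf(a, matrix = S)), 2 / 3)
  expect_equal(scoreValues(scoreLandgraf(alnFromColumns("AAAA"),
                                         matrix = S)), 0)
  lB <- scoreValues(scoreLandgraf(alnFromColumns("AAAB"), matrix = S))
  lC <- scoreValues(scoreLandgraf(alnFromColumns("AAAC"), matrix = S))
  expect_gt(lB, 0)
  expect_gt(lC, lB)   # lower S(A, .) substitution increases L strictly

  expect_error(scoreLandgraf(alnFromColumns("AD"), matrix = S), "absent")
})

test_that("Landgraf with the bundled Gonnet matrix behaves on real residues", {
  g <- gonnetMatrix()
  expect_equal(dim(g), c(20, 20))
  expect_equal(g["A", "A"], 2.4)
  expect_equal(g["W", "W"], 14.2)
  a <- generateMsa(6, 12, conservation = 0.7, seed = 2,
                   gapBlocks = list(list(cols = 1:2, fraction = 0.5)))
  v <- scoreValues(scoreLandgraf(a))
  expect_true(all(is.finite(v)))
  expect_true(all(v >= -1e-12))
})

test_that("grouping mode reduces the alphabet and never raises entropy", {
  sch <- testGroupingScheme()
  a <- aln(s1 = "AVLK", s2 = "IMFR")
  g <- applyGrouping(a, sch)
  expect_identical(unname(alnStrings(g)), c("hhh+", "hhh+"))

  # identity scheme leaves the alignment unchanged
  idsch <- setNames(AA20, AA20)
  expect_identical(alnStrings(applyGrouping(a, idsch)), alnStrings(a))

  for (seed in 1:25) {
    b <- generateMsa(8, 12, conservation = runif(12), seed = seed,
                     gapBlocks = list(list(cols = 3:4, fraction = 0.3)))
    hg <- scoreValues(scoreConservation(applyGrouping(b, sch), "shannon"))
    h <- scoreValues(scoreConservation(b, "shannon"))
    expect_true(all(hg <= h + 1e-12))
  }
})

test_that("grouping schemes load from two-column text", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# residue group", "A h", "V h", "K +"), f)
  sch <- readGroupingScheme(f)
  expect_identical(sch[["A"]], "h")
  expect_identical(sch[["K"]], "+")
  expect_error(applyGrouping(aln(s1 = "AC", s2 = "AC"), sch), "lacks")
})
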