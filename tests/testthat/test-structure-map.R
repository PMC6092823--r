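test_that("compartment tables parse numbers, names and features", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("number\tname\tburial",
               "101\tLEU\t0.5", "104\tPHE\t0.9", "380\tTRP\t0.1"), f)
  comp <- readCompartmentTable(f, name = "t2")
  expect_s4_class(comp, "Compartment")
  expect_identical(compartmentName(comp), "t2")
  df <- compartmentResidues(comp)
  expect_equal(df$number, c(101L, 104L, 380L))
  expect_equal(df$burial, c(0.5, 0.9, 0.1))

  writeLines(c("number name", "101 LEU", "101 PHE"), f)
  expect_error(readCompartmentTable(f), "duplicate")
  writeLines(c("number name val", "101 LEU abc"), f)
  expect_error(readCompartmentTable(f), "non-numeric.*row 1")
  writeLines(c("number name", "101 ZZZ"), f)
  expect_error(readCompartmentTable(f), "invalid residue")
  # a missing feature cell warns but parses
  writeLines(c("number\tname\tval", "101\tLEU\t0.5", "104\tPHE\t"), f)
  expect_warning(comp2 <- readCompartmentTable(f), "missing")
  expect_true(is.na(compartmentResidues(comp2)$val[2]))
})

test_that("REMARK 465 parsing keeps only the requested chain", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    TEST",
               "REMARK 465",
               "REMARK 465 MISSING RESIDUES",
               "REMARK 465   M RES C SSSEQI",
               "REMARK 465     MET A     5",
               "REMARK 465     GLY A     6",
               "REMARK 465     ALA B    12",
               "END"), pdb)
  miss <- readMissingResidues(pdb, "A")
  expect_equal(miss$number, c(5L, 6L))
  expect_equal(miss$resname, c("MET", "GLY"))
  expect_equal(nrow(readMissingResidues(pdb, "C")), 0L)

  writeLines(c("REMARK 465     MET A     5A"), pdb)
  expect_error(readMissingResidues(pdb, "A"), "insertion code")
})

test_that("sequential/author conversion follows the skip rule", {
  expect_equal(sequentialToAuthor(4, c(5, 6)), 4L)
  expect_equal(sequentialToAuthor(5, c(5, 6)), 7L)
  expect_equal(sequentialToAuthor(1:8, c(5, 6)),
               c(1L, 2L, 3L, 4L, 7L, 8L, 9L, 10L))
  expect_equal(authorToSequential(sequentialToAuthor(1:8, c(5, 6)),
                                  c(5, 6)), 1:8)
  expect_error(authorToSequential(5, c(5, 6)), "missing")
})

test_that("numbering correction is identity without missing residues", {
  fx <- generateStructureFixture(20, missing = integer(0),
                                 compartment = c(2, 7, 11), seed = 3)
  comp <- readCompartmentTable(fx$compartmentFile)
  expect_message(fixed <- correctNumbering(comp, fx$pdbFile, "A"),
                 "unchanged")
  expect_equal(compartmentResidues(fixed)$number,
               compartmentResidues(comp)$number)
})

test_that("residue maps are strictly monotone and error on all-gap rows", {
  a <- aln(ref = "A-CD", s2 = "ACCD")
  map <- buildResidueMap(a, "ref")
  expect_equal(map@columns, c(1L, 3L, 4L))
  expect_error(buildResidueMap(a, "nope"), "unknown")
  b <- aln(ref = "---", s2 = "ACD", s3 = "ACD")
  expect_error(buildResidueMap(b, "ref"), "all gaps")

  # un-gapping the mapped columns recovers the 1..L identity
  g <- generateMsa(4, 30, seed = 8,
                   gapBlocks = list(list(cols = 5:9, fraction = 0.5)))
  for (id in seqIds(g)) {
    row <- alnMatrix(g)[id, ]
    if (all(row == "-")) next
    mp <- buildResidueMap(g, id)
    expect_identical(row[mp@columns] != "-", rep(TRUE, length(mp@columns)))
    expect_equal(length(mp@columns), sum(row != "-"))
    expect_true(all(diff(mp@columns) > 0))
  }
})

test_that("structure fixtures round-trip through correction and mapping", {
  for (seed in 1:5) {
    nRes <- 30L
    missing <- sort(sample(5:25, 4))
    fx <- generateStructureFixture(nRes, missing = missing,
                                   compartment = c(3, 8, 15, 20),
                                   seed = seed)
    # alignment: reference (with gap columns inserted) over random partners
    ref <- strsplit(fx$refSeq, "")[[1]]
    set.seed(seed + 500)
    gapAt <- sort(sample(nRes + 5L, 5L))
    cols <- setdiff(seq_len(nRes + 5L), gapAt)
    m <- matrix("-", nrow = 2, ncol = nRes + 5L,
                dimnames = list(c("ref", "other"), NULL))
    m["ref", cols] <- ref
    m["other", ] <- sample(AA20, nRes + 5L, replace = TRUE)
    a <- ProteinAlignment(m, normalize = FALSE)

    comp <- readCompartmentTable(fx$compartmentFile)
    fixed <- correctNumbering(comp, fx$pdbFile, "A")
    expect_equal(compartmentResidues(fixed)$number, fx$authorNumbers)
    map <- buildResidueMap(a, "ref")
    expect_no_warning(colsMapped <- compartmentColumns(map, fixed, a = a))
    # the alignment symbol at every mapped column matches the table's name
    expect_identical(unname(alnMatrix(a)["ref", colsMapped]),
                     ref[fx$authorNumbers])
  }
})

test_that("out-of-range compartment residues are reported", {
  a <- aln(ref = "ACD", s2 = "ACD")
  map <- buildResidueMap(a, "ref")
  comp <- new("Compartment", name = "t",
              residues = data.frame(number = c(2L, 9L),
                                    name = c("CYS", "TRP")))
  expect_error(compartmentColumns(map, comp), "beyond.*9")
})
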