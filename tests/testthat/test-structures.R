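fixtureScenario <- function(seed = 91)
  makeScenario(nSites = 9, cardinality = 21, Mb = 0, Md = 0, strength = 2,
               focusPositions = 4:8, seed = seed)

test_that("synthetic PDB fixtures round-trip through parsing", {
  sc <- fixtureScenario()
  dirf <- withr::local_tempdir()
  fx <- makeContactFixtures(sc, 3, seed = 92, dir = dirf)
  cx <- parseStructure(fx$path[1], roleMap = list(P = "peptide",
                                                  T = "tcrb"))
  pep <- cx$chains[["P"]]
  expect_equal(pep$sequence, fx$sequence[1])
  expect_equal(pep$atoms$x, 8 * (1:9))
  expect_equal(pep$atoms$rank, 1:9)
})

test_that("hydrogens are excluded and occupancy picks one conformer", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA P   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  HA  ALA P   1       0.500   0.000   0.000  1.00  0.00           H",
    "ATOM      3  CA AGLY P   2       8.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CA BGLY P   2       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      5  CA  GLY T   1       0.000   3.000   0.000  1.00  0.00           C",
    "END"), f)
  cx <- suppressWarnings(
    parseStructure(f, roleMap = list(P = "peptide", T = "other")))
  pep <- cx$chains[["P"]]
  expect_equal(nrow(pep$atoms), 2L)          # no hydrogen
  expect_equal(pep$atoms$x[2], 9)            # highest occupancy conformer
  expect_equal(pep$sequence, "AG")
})

test_that("contact rule is boundary-inclusive and monotone in the cutoff", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA P   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY P   2       8.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  LEU P   3      16.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY T   1       0.000   4.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  GLY T   2       8.000   3.000   0.000  1.00  0.00           C",
    "END"), f)
  cx <- suppressWarnings(
    parseStructure(f, roleMap = list(P = "peptide", T = "other")))
  # atom at exactly 4.0 A counts at cutoff 4.0 (<= rule)
  e4 <- computeContacts(cx, "peptide", "other", cutoff = 4.0)
  expect_equal(e4$contacts[[1]], c(1L, 2L))
  e3 <- computeContacts(cx, "peptide", "other", cutoff = 3.5)
  expect_equal(e3$contacts[[1]], 2L)
  # raising the cutoff never removes contacts
  prev <- integer(0)
  for (co in c(2, 3, 3.5, 4, 5, 9)) {
    cur <- computeContacts(cx, "peptide", "other", cutoff = co)$contacts[[1]]
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("contacts are invariant under rigid motions of the complex", {
  sc <- fixtureScenario(93)
  dirf <- withr::local_tempdir()
  fx <- makeContactFixtures(sc, 1, seed = 94, dir = dirf)
  cx <- parseStructure(fx$path[1], roleMap = list(P = "peptide",
                                                  T = "other"))
  before <- computeContacts(cx, "peptide", "other", 4.0)$contacts[[1]]
  # rotate all coordinates by an arbitrary rotation + translation
  th <- 0.83; ph <- 1.21
  R1 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3)
  R <- R1 %*% R2
  for (ch in names(cx$chains)) {
    xyz <- as.matrix(cx$chains[[ch]]$atoms[, c("x", "y", "z")])
    moved <- xyz %*% R + matrix(c(12.3, -4.5, 77), nrow(xyz), 3,
                                byrow = TRUE)
    cx$chains[[ch]]$atoms[, c("x", "y", "z")] <- moved
  }
  after <- computeContacts(cx, "peptide", "other", 4.0)$contacts[[1]]
  expect_equal(after, before)
})

test_that("mmCIF and PDB renderings of the same fixture parse identically", {
  sc <- fixtureScenario(95)
  dirf <- withr::local_tempdir()
  fx <- makeContactFixtures(sc, 1, seed = 96, dir = dirf)
  cif <- writeFixtureCIF(file.path(dirf, "fixture.cif"), fx$sequence[1],
                         fx$contacts[[1]])
  cxP <- parseStructure(fx$path[1], roleMap = list(P = "peptide",
                                                   T = "other"))
  cxC <- parseStructure(cif, roleMap = list(P = "peptide", T = "other"))
  expect_equal(cxP$chains[["P"]]$sequence, cxC$chains[["P"]]$sequence)
  expect_equal(cxP$chains[["P"]]$atoms, cxC$chains[["P"]]$atoms)
  expect_equal(computeContacts(cxP, "peptide", "other", 4)$contacts,
               computeContacts(cxC, "peptide", "other", 4)$contacts)
})

test_that("CDR3 span detection and span-relative contacts work", {
  f <- tempfile(fileext = ".pdb")
  # beta-like chain: xxCASSFxxFGQGxx -> CDR3 = CASSF...F (C..FGQG F)
  seqB <- "GGCASSFLGFGQGAA"
  aa3 <- vapply(strsplit(seqB, "")[[1]], bio3d::aa123, character(1))
  lines <- vapply(seq_along(aa3), function(i)
    sprintf("ATOM  %5d  CA  %3s B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, aa3[i], i, 8 * i, 0, 0), character(1))
  # peptide partner atom 3 A from beta residue 5 (S, inside CDR3)
  lines <- c(lines,
    sprintf("ATOM  %5d  CA  %3s Q%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            99L, "ALA", 1L, 40, 3, 0),
    "END")
  writeLines(lines, f)
  cx <- suppressWarnings(
    parseStructure(f, roleMap = list(B = "tcrb", Q = "peptide")))
  expect_equal(cx$chains[["B"]]$cdr3Span, c(3L, 10L))   # C...F (FGQG)
  ce <- computeContacts(cx, "tcrb", "peptide", 4.0)
  expect_equal(ce$sequence, "CASSFLGF")
  expect_equal(ce$contacts[[1]], 3L)        # residue 5 -> CDR3 position 3
})

test_that("deduplication keeps unique sequence-contact combinations", {
  e <- data.frame(sequence = c("AAAA", "AAAA", "AAAA", "CCCC"))
  e$contacts <- list(c(1L, 2L), c(1L, 2L), c(2L, 3L), 1L)
  dd <- deduplicateEntries(e)
  expect_equal(nrow(dd), 3L)                 # same seq, different contacts kept
  expect_identical(deduplicateEntries(dd), dd)   # idempotent
  empty <- e[0, , drop = FALSE]
  expect_equal(nrow(deduplicateEntries(empty)), 0L)
})

test_that("multiplicities count one-substitution neighbours and give Reff", {
  e <- data.frame(sequence = c("AAAA", "AAAB", "CCCC"))
  e$contacts <- list(1L, 2L, 3L)
  me <- contactMultiplicities(e)
  expect_equal(me$n_sigma, c(2L, 2L, 1L))
  expect_equal(attr(me, "Reff"), 2)
  # distant sequences: all 1, Reff = R
  e2 <- data.frame(sequence = c("AAAA", "GGGG", "CCCC"))
  e2$contacts <- list(1L, 2L, 3L)
  m2 <- contactMultiplicities(e2)
  expect_equal(m2$n_sigma, rep(1L, 3))
  expect_equal(attr(m2, "Reff"), 3)
  # identical sequence with different contacts: each counts the other
  e3 <- data.frame(sequence = c("AAAA", "AAAA"))
  e3$contacts <- list(1L, 2L)
  expect_true(all(contactMultiplicities(e3)$n_sigma >= 2L))
  # Reff <= R always on random entry sets
  set.seed(17)
  for (k in 1:5) {
    seqs <- vapply(1:6, function(i)
      paste(sample(c("A", "C", "G"), 4, replace = TRUE), collapse = ""),
      character(1))
    ex <- data.frame(sequence = seqs); ex$contacts <- as.list(1:6)
    expect_lte(attr(contactMultiplicities(ex), "Reff"), 6)
  }
})

test_that("CDR3 anchor-distance conversions round-trip", {
  for (L in c(12L, 15L, 20L)) {
    pos <- seq_len(L)
    for (side in c("left", "right")) {
      d <- cdr3AnchorDistance(pos, L, side)
      expect_equal(cdr3PositionFromAnchor(d, L, side), pos)
    }
  }
  expect_equal(cdr3AnchorDistance(1L, 13L, "left"), 0L)
  expect_equal(cdr3AnchorDistance(13L, 13L, "right"), 0L)
})
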