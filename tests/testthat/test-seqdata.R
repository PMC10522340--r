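test_that("sequence reading handles FASTA, plain text and tables", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "NLVPMVATV", ">b", "GILGFVFTL"), fa)
  r <- readSequences(fa, "fasta")
  expect_equal(r$sequence, c("NLVPMVATV", "GILGFVFTL"))

  pl <- tempfile()
  writeLines(c("AAAA", "AAAA"), pl)          # duplicates are kept
  expect_equal(nrow(readSequences(pl, "plain")), 2L)

  tb <- tempfile(fileext = ".tsv")
  writeLines(c("cdr3\tv.segm\tj.segm", "CASSF\tTRBV19\tTRBJ2-7"), tb)
  r3 <- readSequences(tb, "table")
  expect_equal(r3$sequence, "CASSF")
  expect_equal(r3$v_gene, "TRBV19")
  expect_equal(r3$j_gene, "TRBJ2-7")

  bad <- tempfile()
  writeLines(c("ACDEF", "ACDXZ"), bad)
  expect_error(readSequences(bad, "plain"), "entry/row: 2")
  expect_error(readSequences(tempfile(), "plain"), "not found")
})

test_that("immunogenicity filtering follows the qualitative-measure rules", {
  tab <- data.frame(
    `Description` = c("NLVPMVATV", "NLVPMVATV", "GILGFVFTL", "AAAAAAAAKAAL",
                      "LLFGYPVYV", "SLLMWITQC", "SLLMWITQC", "KLGGALQAK",
                      "RLRAEAQVK"),
    `Allele Name` = rep("HLA-A*02:01", 9),
    `Qualitative Measure` = c("Positive", "Negative", "Positive-High",
                              "Positive", "Negative", "Positive-Low",
                              "Negative", "Positive", "Positive"),
    `Antigen Epitope Relation` = c(rep("Epitope", 8), "Structure"),
    `In Vitro Process Type` = c(rep("", 7), "Restimulation in vitro", ""),
    check.names = FALSE)
  pos <- filterImmunogenicityTable(tab, "HLA-A*02:01", "immunogenic")
  neg <- filterImmunogenicityTable(tab, "HLA-A*02:01", "non_immunogenic")
  # mixed Positive/Negative peptide excluded from both classes
  expect_false("NLVPMVATV" %in% pos$sequence)
  expect_false("NLVPMVATV" %in% neg$sequence)
  # purely positive peptide retained once
  expect_true("GILGFVFTL" %in% pos$sequence)
  # 12-mer excluded regardless of measure
  expect_false("AAAAAAAAKAAL" %in% pos$sequence)
  # purely negative peptide is non-immunogenic
  expect_true("LLFGYPVYV" %in% neg$sequence)
  # Positive-Low alongside Negative blocks the non-immunogenic class
  expect_false("SLLMWITQC" %in% neg$sequence)
  expect_false("SLLMWITQC" %in% pos$sequence)   # no Positive/Positive-High
  # restimulation and non-Epitope rows are dropped
  expect_false("KLGGALQAK" %in% pos$sequence)
  expect_false("RLRAEAQVK" %in% pos$sequence)
  # the two modes are disjoint
  expect_length(intersect(pos$sequence, neg$sequence), 0)
  expect_error(filterImmunogenicityTable(tab[, -3], "HLA-A*02:01"),
               "Qualitative Measure")
})

test_that("peptide aligner is the identity on 9-mers and places gaps by profile likelihood", {
  set.seed(3)
  bg <- vapply(1:60, function(i)
    paste(sample(head(aminoAlphabet(), 20), 9, replace = TRUE),
          collapse = ""), character(1))
  al <- buildProfileAligner(bg, 9)
  a9 <- alignSequences(al, bg[1:3])
  expect_equal(decodeSequences(a9), bg[1:3])

  # 8-mer: oracle enumerates all 9 gap placements and scores with the profile
  pep8 <- "ACDEFGHI"
  got <- alignSequences(al, pep8)[1, ]
  st8 <- match(strsplit(pep8, "")[[1]], aminoAlphabet())
  cands <- lapply(1:9, function(g) append(st8, gapIndex(), after = g - 1))
  scores <- vapply(cands, function(s)
    sum(al@logProfile[cbind(1:9, s)]), numeric(1))
  expect_equal(got, cands[[which.max(scores)]])
  # gap removal recovers the input
  expect_equal(decodeSequences(rbind(got), dropGaps = TRUE), pep8)

  # alignment is deterministic and idempotent in effect on 9-mer output
  expect_identical(alignSequences(al, pep8), alignSequences(al, pep8))
  nine <- decodeSequences(alignSequences(al, "ACDEFGHIK"))
  expect_identical(nine, "ACDEFGHIK")

  expect_error(buildProfileAligner(c(bg, "ACDEFGH"), 9), "length range")
  expect_error(alignSequences(al, "ACDEFG"), "length")
})

test_that("CDR3 alignment anchors both ends with central gaps", {
  al <- new("ProfileAligner", targetLength = 20L,
            logProfile = matrix(log(1 / 21), 20, 21), mode = "cdr3")
  # length 12: left block of 6, 8 central gaps, right block of 6
  got <- alignSequences(al, "CASSFLGTEAFF")[1, ]
  expect_equal(got[7:14], rep(gapIndex(), 8))
  expect_equal(decodeSequences(rbind(got), dropGaps = TRUE), "CASSFLGTEAFF")
  # single 5-mer: 3 left, 15 gaps, 2 right
  g5 <- alignSequences(al, "CASSF")[1, ]
  expect_equal(sum(g5 == gapIndex()), 15L)
  expect_equal(decodeSequences(rbind(g5), dropGaps = TRUE), "CASSF")
  # gene sites appended with the documented cardinalities
  wg <- alignSequences(al, "CASSFLGTEAFF", withGenes = TRUE,
                       vGene = "TRBV19", jGene = "TRBJ2-7")
  expect_equal(ncol(wg), 22L)
  expect_equal(cardinalities(wg), c(rep(21L, 20), 48L, 13L))
  expect_error(alignSequences(al, "CASSF", withGenes = TRUE,
                              vGene = "TRBV99", jGene = "TRBJ2-7"),
               "unknown V gene")
})

test_that("similarity reweighting counts clusters above the identity threshold", {
  # three identical sequences: each weight 1/3
  s <- encodeSequences(rep("NLVPMVATV", 3))
  expect_equal(similarityReweight(s), rep(1 / 3, 3))
  # two sequences differing at 5 of 9 positions: identity 4/9, both weight 1
  s2 <- encodeSequences(c("NLVPMVATV", "NLVPQQQQQ"))
  expect_equal(similarityReweight(s2), c(1, 1))
  # A and B one substitution apart (8/9 > 0.8), C four away from both:
  # brute-force pairwise identity oracle gives (1/2, 1/2, 1)
  seqs <- c("NLVPMVATV", "NLVPMVATI", "NLVPQQQQQ")
  s3 <- encodeSequences(seqs)
  idOracle <- function(a, b)
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  wOracle <- vapply(seqs, function(a)
    1 / sum(vapply(seqs, function(b) idOracle(a, b) > 0.8, logical(1))),
    numeric(1))
  expect_equal(similarityReweight(s3), unname(wOracle))
  expect_equal(unname(wOracle), c(1 / 2, 1 / 2, 1))
  expect_error(similarityReweight(s3[0, , drop = FALSE]), "empty")
})

test_that("reweighting weights are in (0,1] and sum below n unless no pair is similar", {
  set.seed(12)
  for (rep in 1:5) {
    base <- paste(sample(head(aminoAlphabet(), 20), 9, replace = TRUE),
                  collapse = "")
    seqs <- c(base, vapply(1:6, function(i) {
      s <- strsplit(base, "")[[1]]
      k <- sample(9, sample(0:4, 1))
      s[k] <- sample(head(aminoAlphabet(), 20), length(k), replace = TRUE)
      paste(s, collapse = "")
    }, character(1)))
    w <- similarityReweight(encodeSequences(seqs))
    expect_true(all(w > 0 & w <= 1))
    expect_lte(sum(w), length(seqs))
    if (all(w == 1)) {
      X <- diffrbm:::oneHot(encodeSequences(seqs))
      m <- as.matrix(Matrix::tcrossprod(X)) / 9
      expect_true(all(m[upper.tri(m)] <= 0.8))
    }
  }
})

test_that("gene catalogs have the fixed cardinalities", {
  cats <- geneCatalogs()
  expect_length(cats$v, 48L)
  expect_length(cats$j, 13L)
  expect_false(anyDuplicated(cats$v) > 0)
  expect_false(anyDuplicated(cats$j) > 0)
})
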