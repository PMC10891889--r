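test_that("local protein alignment is exact and local", {
  expect_equal(localProteinAlign("MKVLHDE", "MKVLHDE")$identity, 100)
  tail <- localProteinAlign("MKV", "MKVWWWWPPPP")
  expect_equal(tail$identity, 100)   # local: covers the MKV prefix
  expect_error(localProteinAlign("", "MKV"), "nonempty")
  set.seed(17)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    p1 <- paste(sample(aa, sample(8:30, 1), TRUE), collapse = "")
    p2 <- paste(sample(aa, sample(8:30, 1), TRUE), collapse = "")
    expect_equal(localProteinAlign(p1, p2)$score,
                 oracleLocalProteinScore(p1, p2), info = i)
  }
})

test_that("identical proteomes pair one-to-one under RBH", {
  op <- makeOrthologPair(8, identityPercent = 100, seed = 2)
  rbh <- reciprocalBestHits(op$proteomeA, op$proteomeB)
  expect_equal(nrow(rbh), 8L)
  expect_identical(sub("gB", "gA", rbh$locus_b), rbh$locus_a)
  expect_true(all(rbh$identity == 100))
})

test_that("planted orthologs at 60% identity are recovered exactly; decoys yield none", {
  op <- makeOrthologPair(15, identityPercent = 60, nDecoys = 8, seed = 3)
  rbh <- reciprocalBestHits(op$proteomeA, op$proteomeB)
  expect_equal(nrow(rbh), 15L)
  expect_identical(sort(rbh$locus_a), sort(op$truth$locus_a))
  # RBH is symmetric: transpose equality
  rbh_t <- reciprocalBestHits(op$proteomeB, op$proteomeA)
  expect_setequal(paste(rbh$locus_a, rbh$locus_b),
                  paste(rbh_t$locus_b, rbh_t$locus_a))
  # decoy-only null, several seeds
  for (s in 1:3) {
    opn <- makeOrthologPair(2, identityPercent = 100, nDecoys = 8,
                            seed = 200 + s)
    null <- reciprocalBestHits(opn$proteomeA[-(1:2)], opn$proteomeB[-(1:2)])
    expect_equal(nrow(null), 0L, info = s)
  }
})

test_that("parity points capture collinearity and rearrangement", {
  pairs <- data.frame(locus_a = sprintf("a%02d", 1:10),
                      locus_b = sprintf("b%02d", 1:10),
                      stringsAsFactors = FALSE)
  ordA <- sprintf("a%02d", 1:10)
  ordB <- sprintf("b%02d", 1:10)
  self <- parityPoints(pairs, ordA, ordB)
  expect_equal(self$correlation, 1.0)
  expect_equal(self$points$rank_a, self$points$rank_b)
  rev <- parityPoints(pairs, ordA, rev(ordB))
  expect_equal(rev$correlation, -1.0)
  # one inverted block -> two collinear segments, correlation < 1
  ordB_inv <- ordB[c(1:3, 7:4, 8:10)]
  inv <- parityPoints(pairs, ordA, ordB_inv)
  expect_lt(inv$correlation, 1)
  seg1 <- inv$points[inv$points$rank_a %in% 1:3, ]
  expect_equal(seg1$rank_b, seg1$rank_a)
  seg2 <- inv$points[inv$points$rank_a %in% 4:7, ]
  expect_equal(diff(seg2$rank_b), rep(-1, 3))
})

test_that("core-gene presence is an RBH existence check", {
  op <- makeOrthologPair(10, identityPercent = 70, seed = 5)
  refs <- op$proteomeB
  names(refs) <- sprintf("fam%02d", 1:10)
  chk <- coreGeneCheck(op$proteomeA, refs)
  expect_equal(chk$n_present, 10L)
  # references against themselves: all present
  self <- coreGeneCheck(refs, refs)
  expect_equal(self$n_present, 10L)
  # a proteome lacking the references
  none <- coreGeneCheck(op$proteomeA[1:3], setNames(
    vapply(1:4, function(i) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1]], 80, TRUE),
                                  collapse = ""), ""),
    paste0("f", 1:4)))
  expect_equal(none$n_present, 0L)
  expect_error(coreGeneCheck(op$proteomeA, character()), "empty")
})

test_that("linear-space whole-genome identity equals the quadratic oracle", {
  expect_equal(as.numeric(wholeGenomeIdentity("ACGTACGTAA", "ACGTACGTAA")),
               100)
  expect_equal(as.numeric(wholeGenomeIdentity("AAAA", "TTTT")), 0)
  set.seed(33)
  for (i in 1:20) {
    a <- randomDna(sample(20:500, 1))
    b <- randomDna(sample(20:500, 1))
    expect_equal(attr(wholeGenomeIdentity(a, b), "score"),
                 oracleGlobalScore(a, b, 5, -4, 16, 4), info = i)
  }
  # symmetry and range on diverged genomes
  g1 <- randomDna(2000, seed = 3)
  g2 <- evolveSequence(g1, 0.2, seed = 4)
  i12 <- as.numeric(wholeGenomeIdentity(g1, g2))
  i21 <- as.numeric(wholeGenomeIdentity(g2, g1))
  expect_equal(i12, i21)
  expect_gt(i12, 75); expect_lt(i12, 90)
})

test_that("supermatrix concatenation preserves columns and partitions", {
  fams <- list(
    f1 = c(t1 = "MK-V", t2 = "MKAV"),
    f2 = c(t2 = "DERRKN", t1 = "DE--KN"))
  sm <- concatenateCoreAlignments(fams)
  expect_equal(unname(nchar(sm$supermatrix)), c(10L, 10L))
  expect_equal(sm$partitions$start, c(1L, 5L))
  expect_equal(sm$partitions$end, c(4L, 10L))
  expect_identical(sm$supermatrix[["t1"]], "MK-VDE--KN")
  # partitions tile every column exactly once
  cov <- unlist(Map(seq, sm$partitions$start, sm$partitions$end))
  expect_identical(as.integer(cov), 1:10)
  # single family: identity
  one <- concatenateCoreAlignments(fams[1])
  expect_identical(one$supermatrix[["t2"]], "MKAV")
  # taxon mismatch errors with the missing taxon named
  bad <- list(f1 = c(t1 = "MKV"), f2 = c(t2 = "DEK"))
  expect_error(concatenateCoreAlignments(bad), "t1")
})
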