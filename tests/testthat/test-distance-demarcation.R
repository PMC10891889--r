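test_that("global alignment is optimal against the full-matrix oracle", {
  expect_equal(globalAlignPair("ACGT", "ACGT")$score, 20)
  expect_error(globalAlignPair("ACGT", ""), "nonempty")
  p <- globalAlignPair("ACGT", "AGT")
  expect_equal(nchar(p$seq_a), nchar(p$seq_b))
  set.seed(21)
  for (i in 1:15) {
    a <- randomDna(sample(5:60, 1)); b <- randomDna(sample(5:60, 1))
    expect_equal(globalAlignPair(a, b)$score,
                 oracleGlobalScore(a, b, 5, -4, 10, 0.5), info = i)
  }
})

test_that("K2P distance follows the closed form with pairwise deletion", {
  x <- strrep("A", 100)
  y <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  r <- k2pDistance(list(seq_a = x, seq_b = y))
  expect_equal(r@P, 0.10)
  expect_equal(r@Q, 0.05)
  expect_equal(r@nSites, 100L)
  expect_equal(r@distance, 0.1702, tolerance = 1e-4 / 0.1702)
  # identical sequences
  r0 <- k2pDistance(list(seq_a = "ACGTACGT", seq_b = "ACGTACGT"))
  expect_equal(r0@distance, 0)
  # gaps and N excluded pairwise
  rg <- k2pDistance(list(seq_a = "ACGT-NAC", seq_b = "AC-TAAAC"))
  expect_equal(rg@nSites, 5L)
  # all-gap comparison signals an undefined result
  expect_error(k2pDistance(list(seq_a = "ACGT", seq_b = "----")),
               "no comparable sites")
  # saturation: defined = FALSE
  sat <- k2pDistance(list(seq_a = strrep("A", 10),
                          seq_b = strrep("G", 10)))
  expect_false(sat@defined)
  expect_true(is.na(sat@distance))
})

test_that("K2P agrees with ape and reduces to Jukes-Cantor when balanced", {
  # equal substitution classes: P = p/3, Q = 2p/3 -> K2P == JC exactly
  p <- 0.12
  x <- strrep("A", 300)
  y <- paste0(strrep("G", 12), strrep("C", 12), strrep("T", 12),
              strrep("A", 264))
  d <- k2pDistance(list(seq_a = x, seq_b = y))@distance
  expect_equal(d, -0.75 * log(1 - 4 * p / 3), tolerance = 1e-9)
  skip_if_not_installed("ape")
  set.seed(14)
  anc <- randomDna(4000)
  mut <- evolveSequence(anc, 0.2, seed = 5)
  m <- rbind(strsplit(tolower(anc), "")[[1]], strsplit(tolower(mut), "")[[1]])
  rownames(m) <- c("a", "b")
  dape <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                                   pairwise.deletion = TRUE))
  dmine <- k2pDistance(list(seq_a = anc, seq_b = mut))@distance
  expect_equal(dmine, dape, tolerance = 1e-9)
})

test_that("K2P distance is symmetric and monotone in P", {
  set.seed(4)
  a <- randomDna(500); b <- evolveSequence(randomDna(500), 0.1, seed = 2)
  r1 <- k2pDistance(list(seq_a = a, seq_b = b))
  r2 <- k2pDistance(list(seq_a = b, seq_b = a))
  expect_equal(r1@distance, r2@distance)
  dOf <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  Ps <- seq(0.01, 0.3, by = 0.01)
  ds <- vapply(Ps, dOf, 1, Q = 0.1)
  expect_true(all(diff(ds) > 0))
})

test_that("demarcation verdicts follow the 0.05 subs/site rule", {
  expect_identical(
    demarcateSpecies(list(polh = 0.31, lef8 = 0.28, lef9 = 0.25))$verdict,
    "novel")
  expect_identical(
    demarcateSpecies(list(polh = 0.001, lef8 = 0.002, lef9 = 0.001))$verdict,
    "not_novel")
  expect_identical(
    demarcateSpecies(list(polh = 0.30, lef8 = 0.01))$verdict,
    "inconclusive")
  # boundary: exactly at the threshold is not novel
  expect_identical(demarcateSpecies(list(polh = 0.05))$verdict, "not_novel")
  # missing markers are reported; wrong input errors
  v <- demarcateSpecies(list(polh = 0.2))
  expect_setequal(v$missing_markers, c("lef8", "lef9"))
  expect_error(demarcateSpecies(list()), "no marker")
  expect_error(demarcateSpecies(list(foo = 0.2)), "at least one")
  # K2PResult inputs and undefined distances
  r <- k2pDistance(list(seq_a = strrep("A", 20), seq_b = strrep("A", 20)))
  expect_identical(demarcateSpecies(list(polh = r))$verdict, "not_novel")
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(8)
  a <- randomDna(600)
  b <- evolveSequence(a, 0.15, seed = 3)
  D <- k2pDistanceMatrix(c(t1 = a, t2 = b, t3 = a))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D["t1", "t3"], 0)
  expect_gt(D["t1", "t2"], 0.1)
  expect_length(attr(D, "results"), 3L)   # n(n-1)/2 unique pairs
  expect_error(k2pDistanceMatrix(c(x = "ACGT")), "two sequences")
  # PHYLIP output round-trips the matrix shape
  f <- withr::local_tempfile(fileext = ".dist")
  writePhylipMatrix(D, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_length(lines, 4L)
})
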