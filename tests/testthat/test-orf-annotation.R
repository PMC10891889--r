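test_that("no start codon means no ORFs", {
  g <- CircularGenome(strrep("C", 400), topology = "linear")
  expect_equal(nrow(findOrfs(g)), 0L)
  expect_warning(findOrfs(CircularGenome("ATGAAATAA", topology = "linear")),
                 "shorter")
})

test_that("a planted ORF is recovered with exact coordinates", {
  set.seed(1)
  bg <- randomDna(400)
  orfseq <- paste0("ATG", strrep("GCT", 59), "TAA")
  full <- paste0(substr(bg, 1, 100), "TAA", orfseq, substr(bg, 101, 400))
  o <- findOrfs(CircularGenome(full, topology = "linear"), minAa = 50)
  hit <- o[o$start == 104 & o$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length_aa, 60L)
  expect_equal(hit$end, 104L + 3L * 61L - 1L)
  expect_match(hit$translation, "^MA+")
})

test_that("origin-spanning ORFs are found once, against a doubled-sequence oracle", {
  L <- 600L
  v <- strsplit(strrep("C", L), "")[[1]]
  cass <- strsplit(paste0("TAA", "ATG", strrep("AAA", 59), "TAA"), "")[[1]]
  pos <- ((568L + seq_along(cass) - 2L) %% L) + 1L   # ATG lands at 571
  v[pos] <- cass
  g <- CircularGenome(paste(v, collapse = ""))
  o <- findOrfs(g, minAa = 50)
  wrap <- o[o$strand == "+" & o$start == 571L, ]
  expect_equal(nrow(wrap), 1L)
  expect_equal(wrap$end, ((571L + 3L * 61L - 1L - 1L) %% L) + 1L)  # 153
  expect_equal(sum(orfKey(o) == orfKey(wrap)), 1L)   # reported exactly once
  # linearized doubled-sequence oracle: scanning the doubled string
  # linearly finds the same ORF at offset 571
  dd <- CircularGenome(paste0(paste(v, collapse = ""),
                              paste(v, collapse = "")),
                       topology = "linear")
  od <- findOrfs(dd, minAa = 50)
  expect_true(any(od$start == 571L & od$strand == "+"))
})

test_that("findOrfs commutes with reverse complement and rotation", {
  res <- fixtureSmall()
  g <- res$genome
  L <- genomeLength(g)
  o <- findOrfs(g)
  rc <- CircularGenome(as.character(
    Biostrings::reverseComplement(genomeSeq(g))))
  orc <- findOrfs(rc)
  mirrored <- data.frame(start = L - orc$end + 1L, end = L - orc$start + 1L,
                         strand = ifelse(orc$strand == "+", "-", "+"))
  expect_setequal(orfKey(o), orfKey(mirrored))
  rot <- rotateToOrigin(g, 1234L)
  orot <- findOrfs(rot)
  unrot <- data.frame(
    start = ((orot$start + 1234L - 1L - 1L) %% L) + 1L,
    end = ((orot$end + 1234L - 1L - 1L) %% L) + 1L,
    strand = orot$strand)
  expect_setequal(orfKey(o), orfKey(unrot))
})

test_that("reported translations are reproducible from coordinates", {
  res <- fixtureSmall()
  g <- res$genome
  o <- findOrfs(g)
  for (i in sample(nrow(o), min(10, nrow(o)))) {
    nt <- extractSubsequence(g, o$start[i], o$end[i], o$strand[i])
    aa <- sub("\\*$", "", as.character(
      Biostrings::translate(Biostrings::DNAString(nt))))
    expect_identical(aa, o$translation[i])
  }
})

test_that("overlap resolution keeps both ORFs at exactly 75 bp overlap", {
  orfs <- data.frame(
    locus_tag = c("a", "b"), start = c(1L, 826L), end = c(900L, 1100L),
    strand = c("+", "+"), length_aa = c(299L, 90L),
    stringsAsFactors = FALSE)
  # overlap 826..900 = 75 bp exactly -> both retained
  expect_equal(nrow(resolveOverlaps(orfs, 5000L)), 2L)
  # 76 bp overlap -> smaller dropped
  orfs76 <- orfs; orfs76$start[2] <- 825L
  kept <- resolveOverlaps(orfs76, 5000L)
  expect_identical(kept$locus_tag, "a")
  # unless the smaller is a conserved homolog
  kept2 <- resolveOverlaps(orfs76, 5000L, homologHits = "b")
  expect_equal(nrow(kept2), 2L)
})

test_that("overlap resolution is idempotent and tie-breaks deterministically", {
  set.seed(12)
  n <- 15L
  starts <- sort(sample(3000L, n))
  lens <- sample(150:600, n, TRUE)
  orfs <- data.frame(
    locus_tag = sprintf("x%02d", 1:n), start = starts,
    end = pmin(starts + lens, 4000L),
    strand = sample(c("+", "-"), n, TRUE),
    stringsAsFactors = FALSE)
  once <- resolveOverlaps(orfs, 4000L)
  twice <- resolveOverlaps(once, 4000L)
  expect_identical(once, twice)
  # equal-length tie: plus strand wins
  tie <- data.frame(locus_tag = c("m", "p"), start = c(10L, 10L),
                    end = c(309L, 309L), strand = c("-", "+"),
                    stringsAsFactors = FALSE)
  expect_identical(resolveOverlaps(tie, 1000L)$locus_tag, "p")
})

test_that("hr masking removes only ORFs fully inside an hr", {
  hrs <- data.frame(start = 1000L, end = 1400L)
  orfs <- data.frame(locus_tag = c("in", "edge", "out"),
                     start = c(1050L, 990L, 2000L),
                     end = c(1350L, 1200L, 2300L),
                     strand = "+", stringsAsFactors = FALSE)
  kept <- maskHrOrfs(orfs, hrs, 5000L)
  expect_setequal(kept$locus_tag, c("edge", "out"))
  expect_identical(maskHrOrfs(orfs, list(), 5000L), orfs)
})

test_that("genome statistics match their definitions", {
  expect_equal(gcPercent(CircularGenome("ATGC")), 50)
  expect_equal(gcPercent(CircularGenome("ATAT")), 0)
  expect_equal(gcPercent(CircularGenome(paste0(strrep("ATGC", 10), "N"))),
               50)  # N excluded
  g <- CircularGenome(strrep("ACGT", 300))
  orfs <- data.frame(locus_tag = c("a", "b"), start = c(1L, 101L),
                     end = c(200L, 400L), strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  st <- genomeStats(g, orfs)
  expect_equal(st$orf_count, 2L)
  expect_equal(st$forward_count + st$reverse_count, st$orf_count)
  expect_equal(st$coding_fraction_percent, 100 * 400 / 1200)  # union
})

test_that("ORF classification assigns the highest-priority class", {
  res <- fixtureSmall()
  o <- findOrfs(res$genome)
  o <- maskHrOrfs(o, res$truth$hrs, genomeLength(res$genome))
  expect_warning(u <- classifyOrfs(o, list()), "empty")
  expect_true(all(u$annotation_class == "unique"))
  refs <- list(core = setNames(o$translation[1], "ref_core"),
               common = setNames(o$translation[c(1, 2)],
                                 c("ref_core2", "ref_common")))
  cl <- classifyOrfs(o, refs)
  expect_identical(cl$annotation_class[1], "core")     # core beats common
  expect_identical(cl$annotation_class[2], "common")
  expect_true(all(cl$annotation_class[-(1:2)] == "unique"))
})
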