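test_that("upstream windows follow the circular and strand conventions", {
  g <- CircularGenome(randomDna(1000, seed = 8))
  # plus-strand ORF at 100: window = positions -180..-1 with wrap
  orf <- list(start = 100L, end = 400L, strand = "+")
  w <- upstreamWindow(g, orf, 180)
  expect_equal(nchar(w), 180L)
  expect_identical(w, extractSubsequence(g, 920, 99, "+"))
  # minus-strand ORF: window is the reverse complement of the
  # downstream plus-strand span
  orfm <- list(start = 100L, end = 400L, strand = "-")
  wm <- upstreamWindow(g, orfm, 180)
  expect_identical(wm, extractSubsequence(g, 401, 580, "-"))
  # linear genome: shortened window with a warning
  lin <- CircularGenome(randomDna(300, seed = 9), topology = "linear")
  expect_warning(wl <- upstreamWindow(lin, list(start = 50L, end = 200L,
                                                strand = "+")),
                 "truncated")
  expect_equal(nchar(wl), 49L)
  # window capped so it cannot run into the ORF itself
  small <- CircularGenome(randomDna(200, seed = 10))
  ws <- upstreamWindow(small, list(start = 50L, end = 109L, strand = "+"))
  expect_equal(nchar(ws), 200L - 60L)
})

test_that("motif scanning equals the brute-force IUPAC oracle on fuzz", {
  motifs <- c("TATAW", "CAKT", "TAATWAA", "DTAAG", "NRYSWKM")
  set.seed(77)
  for (i in 1:30) {
    w <- randomDna(sample(30:200, 1), gc = sample(c(30, 50, 70), 1))
    if (i %% 5 == 0) {  # sprinkle Ns
      v <- strsplit(w, "")[[1]]
      v[sample(length(v), 3)] <- "N"
      w <- paste(v, collapse = "")
    }
    for (m in motifs)
      expect_identical(scanMotif(w, m), oracleScanMotif(w, m),
                       info = paste(i, m))
  }
  expect_error(scanMotif("ACGT", "QQ"), "IUPAC")
  expect_identical(scanMotif(strrep("C", 50), "DTAAG"), integer(0))
})

test_that("N in the window never matches a motif", {
  w <- paste0(strrep("C", 20), "TANAA", strrep("C", 20))
  expect_identical(scanMotif(w, "TATAW"), integer(0))
  expect_identical(scanMotif(w, "TANAA"), integer(0))
})

test_that("promoter classification follows the motif and spacing rules", {
  pad <- function(...) {
    s <- paste0(...)
    paste0(strrep("C", 180 - nchar(s)), s)
  }
  # TATAW + CAKT at spacing 30 -> early
  early <- pad("TATAA", strrep("C", 25), "CATT", strrep("C", 40))
  expect_identical(classifyPromoter(early)$classification, "early")
  # spacing boundaries: 25 and 35 accepted, 24 and 36 not
  for (sp in c(25, 35)) {
    w <- pad("TATAT", strrep("C", sp - 5), "CAGT", strrep("C", 40))
    expect_identical(classifyPromoter(w)$classification, "early", info = sp)
  }
  for (sp in c(24, 36)) {
    w <- pad("TATAT", strrep("C", sp - 5), "CAGT", strrep("C", 40))
    expect_identical(classifyPromoter(w)$classification, "none", info = sp)
  }
  # TAATWAA alone is early evidence
  expect_identical(classifyPromoter(pad("TAATTAA", strrep("C", 50)))$
                     classification, "early")
  # DTAAG alone -> late
  expect_identical(classifyPromoter(pad("ATAAG", strrep("C", 60)))$
                     classification, "late")
  # both kinds -> both; all C -> none
  both <- pad("TATAA", strrep("C", 25), "CATT", strrep("C", 20), "GTAAG",
              strrep("C", 15))
  expect_identical(classifyPromoter(both)$classification, "both")
  expect_identical(classifyPromoter(strrep("C", 180))$classification,
                   "none")
})

test_that("classification ignores sequence outside the window", {
  res <- fixtureSmall()
  g <- res$genome
  orf <- res$truth$orfs[1, ]
  w <- upstreamWindow(g, orf, 180)
  expect_identical(classifyPromoter(w)$classification,
                   classifyPromoter(paste0(w, ""))$classification)
  # same window pasted into a different context classifies identically
  expect_identical(classifyPromoter(w)$classification,
                   res$truth$promoters$class[1])
})

test_that("promoter summary partitions counts and averages representatives", {
  # planted DTAAG at offset -60 in every window
  w <- paste0(strrep("C", 120), "GTAAG", strrep("C", 55))
  expect_equal(nchar(w), 180)
  calls <- lapply(1:5, function(i) classifyPromoter(w, locus_tag = paste0("l", i)))
  s <- promoterSummary(calls)
  expect_equal(unname(s$counts["late"]), 5L)
  expect_equal(sum(s$counts), s$n)
  expect_equal(s$mean_late_offset, -60)
  # all-none input: means undefined
  s0 <- promoterSummary(list(classifyPromoter(strrep("C", 180))))
  expect_equal(unname(s0$counts["none"]), 1L)
  expect_true(is.na(s0$mean_spacing) && is.na(s0$mean_late_offset))
  expect_error(promoterSummary(list()), "no promoter")
})

test_that("class counts always partition fuzzed window sets", {
  set.seed(123)
  calls <- lapply(1:40, function(i) classifyPromoter(randomDna(180, gc = 40)))
  s <- promoterSummary(calls)
  expect_equal(sum(s$counts), 40L)
})
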