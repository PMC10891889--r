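test_that("exact tandem copies are found with exact period and copy number", {
  set.seed(42)
  unit <- randomDna(112)
  seqr <- paste0(randomDna(3000), strrep(unit, 3), randomDna(3000))
  arr <- findTandemRepeats(seqr)
  expect_length(arr, 1L)
  expect_equal(arr[[1]]$period, 112L)
  expect_equal(arr[[1]]$copies, 3L)
  expect_equal(arr[[1]]$mean_identity, 100)
  expect_equal(arr[[1]]$start, 3001)
})

test_that("random sequence yields no tandem arrays (null behavior)", {
  for (s in 1:20) {
    set.seed(1000 + s)
    expect_length(findTandemRepeats(randomDna(10000)), 0L)
  }
})

test_that("diverged copies are recovered with period within 2 bp", {
  mutate <- function(x, rate) {
    v <- strsplit(x, "")[[1]]
    k <- round(rate * length(v))
    pos <- sample(length(v), k)
    v[pos] <- vapply(v[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  }
  set.seed(9)
  unit <- randomDna(130)
  copies4 <- paste0(unit, mutate(unit, 0.05), mutate(unit, 0.05),
                    mutate(unit, 0.05))
  s4 <- paste0(randomDna(2000), copies4, randomDna(2000))
  arr <- findTandemRepeats(s4)
  expect_length(arr, 1L)
  expect_equal(arr[[1]]$copies, 4L)
  expect_lte(abs(arr[[1]]$period - 130L), 2L)
  expect_gte(arr[[1]]$mean_identity, 90)
  # 10% divergence, 4 copies: period still within 2 bp, copies exact
  copies10 <- paste0(unit, mutate(unit, 0.10), mutate(unit, 0.10),
                     mutate(unit, 0.10))
  s10 <- paste0(randomDna(2000), copies10, randomDna(2000))
  arr10 <- findTandemRepeats(s10)
  expect_length(arr10, 1L)
  expect_equal(arr10[[1]]$copies, 4L)
  expect_lte(abs(arr10[[1]]$period - 130L), 2L)
})

test_that("palindrome finder matches the exhaustive oracle on fuzz", {
  norm <- function(df) {
    df <- df[order(df$start, df$end, df$gap),
             c("start", "end", "armLen", "gap", "mismatches")]
    rownames(df) <- NULL
    df
  }
  set.seed(55)
  for (i in 1:15) {
    s <- randomDna(sample(60:200, 1))
    got <- findPalindromes(s, minArm = 5, maxGap = 4, maxMismatch = 2)
    exp <- oraclePalindromes(s, minArm = 5, maxGap = 4, maxMismatch = 2)
    expect_equal(norm(got), norm(exp), info = i)
  }
})

test_that("palindrome basics: perfect hit, homopolymer, revcomp invariance", {
  p <- findPalindromes("AAAATTTT", minArm = 4, maxGap = 0, maxMismatch = 0)
  expect_equal(nrow(p), 1L)
  expect_equal(p$span, 8L)
  expect_equal(p$mismatches, 0L)
  expect_equal(nrow(findPalindromes(strrep("A", 40), minArm = 4,
                                    maxMismatch = 0)), 0L)
  set.seed(66)
  for (i in 1:8) {
    s <- randomDna(120)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- findPalindromes(s); b <- findPalindromes(rc)
    n <- nchar(s)
    mirrored <- data.frame(start = n - b$end + 1L, end = n - b$start + 1L,
                           armLen = b$armLen, gap = b$gap,
                           mismatches = b$mismatches)
    expect_setequal(paste(a$start, a$end, a$armLen, a$mismatches),
                    paste(mirrored$start, mirrored$end, mirrored$armLen,
                          mirrored$mismatches))
  }
})

test_that("hr assembly requires a central palindromic core", {
  res <- fixtureSmall()
  g <- res$genome
  arr <- findTandemRepeats(g)
  hrs <- assembleHrs(arr, g)
  expect_length(hrs, 1L)
  h <- hrs[[1]]
  expect_s4_class(h, "HrLocus")
  expect_equal(nrow(h@units), res$truth$hrs$copies)
  expect_lte(abs(h@start - res$truth$hrs$start), 2L)
  expect_gte(h@palindrome$span, res$truth$hrs$palindrome_span)
  u <- nchar(h@consensus)
  expect_gte(h@palindrome$center, u / 3)
  expect_lte(h@palindrome$center, 2 * u / 3)
  expect_gt(h@atPercent, 50)   # hr units are AT-rich by construction
  # an array without a palindromic core is rejected
  unit <- strrep("A", 100)   # homopolymer: arms can never complement
  fake <- list(list(start = 1, end = 300, period = 100L, copies = 3L,
                    unit_starts = c(1, 101, 201), consensus = unit,
                    identities = rep(100, 3), mean_identity = 100))
  expect_length(assembleHrs(fake, CircularGenome(strrep(unit, 3))), 0L)
  # empty input -> empty output
  expect_length(assembleHrs(list(), g), 0L)
})

test_that("hr report names circular flanking ORFs", {
  res <- fixtureSmall()
  g <- res$genome
  hrs <- assembleHrs(findTandemRepeats(g), g)
  orfs <- assignLocusTags(findOrfs(g))
  rep <- hrReport(hrs, orfs, genomeLength(g))
  expect_equal(nrow(rep), 1L)
  tru <- res$truth$hrs
  up <- orfs$locus_tag[which.min((tru$start - orfs$end - 1) %%
                                   genomeLength(g))]
  expect_identical(rep$upstream_orf, up)
  expect_identical(rep$name, "hr1")
  # BED output is 0-based half-open
  bed <- withr::local_tempfile(fileext = ".bed")
  writeHrBed(hrs, g, bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(fields[2]) + 1L, hrs[[1]]@start)
  expect_equal(as.integer(fields[3]), hrs[[1]]@end)
})
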