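# Shared fixtures and independent brute-force oracles.  Oracles are
# deliberately naive re-implementations (position-by-position scans,
# full DP matrices) kept separate from the package's algorithms.

randomDna <- function(n, gc = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((100 - gc) / 2, (100 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# --- IUPAC motif scan oracle ---------------------------------------------

.IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

oracleScanMotif <- function(window, motif) {
  wl <- strsplit(window, "")[[1L]]
  ml <- strsplit(motif, "")[[1L]]
  hits <- integer()
  if (length(wl) < length(ml)) return(hits)
  for (i in seq_len(length(wl) - length(ml) + 1L)) {
    ok <- TRUE
    for (j in seq_along(ml)) {
      if (!(wl[i + j - 1L] %in% .IUPAC_ORACLE[[ml[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - length(wl) - 1L)
  }
  hits
}

# --- palindrome oracle (exhaustive arm extension) ------------------------

oraclePalindromes <- function(seq, minArm, maxGap, maxMismatch) {
  chars <- strsplit(seq, "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(chars)
  rows <- list()
  for (g in 0:maxGap) for (l in seq_len(n)) {
    kcap <- min(l, n - g - l)
    if (kcap < minArm) next
    mism <- 0L; arm <- 0L; armMism <- 0L
    for (k in seq_len(kcap)) {
      x <- chars[l - k + 1L]; y <- chars[l + g + k]
      match <- x %in% names(comp) && y %in% names(comp) && x == comp[[y]]
      if (!match) mism <- mism + 1L
      if (mism > maxMismatch) break
      arm <- k; armMism <- mism
    }
    if (arm >= minArm)
      rows[[length(rows) + 1L]] <- data.frame(
        start = l - arm + 1L, end = l + g + arm, armLen = arm, gap = g,
        mismatches = armMism)
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      armLen = integer(), gap = integer(),
                      mismatches = integer()))
  do.call(rbind, rows)
}

# --- affine-gap DP oracles (full matrices) -------------------------------

oracleGlobalScore <- function(a, b, match = 5, mismatch = -4,
                              gapOpen = 16, gapExt = 4) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e15
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in B (A char vs -)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in A
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(gapOpen + gapExt * i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(gapOpen + gapExt * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gapOpen - gapExt,
                             X[i, j + 1L] - gapExt,
                             Y[i, j + 1L] - gapOpen - gapExt)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gapOpen - gapExt,
                             Y[i + 1L, j] - gapExt,
                             X[i + 1L, j] - gapOpen - gapExt)
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

oracleLocalProteinScore <- function(p1, p2, gapOpen = 11, gapExt = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  A <- strsplit(p1, "")[[1L]]; B <- strsplit(p2, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e15
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, ] <- 0; M[, 1L] <- 0
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- S[A[i], B[j]]
    M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j], 0) + s
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gapOpen - gapExt,
                             X[i, j + 1L] - gapExt)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gapOpen - gapExt,
                             Y[i + 1L, j] - gapExt)
    best <- max(best, M[i + 1L, j + 1L])
  }
  best
}

# --- cached synthetic fixtures (generated once per test run) -------------

.fixtures <- new.env(parent = emptyenv())

fixtureSmall <- function() {
  if (is.null(.fixtures$small)) {
    spec <- genomeSpec(
      lengthBp = 20000, gcPercent = 45,
      orfPlan = data.frame(
        length_aa = c(100L, 80L, 200L, 60L, 150L, 90L, 120L, 70L),
        strand = c("+", "-", "+", "+", "-", "+", "-", "+"),
        promoter_class = c("early", "late", NA, "both", "none", "late",
                           NA, "early"),
        stringsAsFactors = FALSE),
      hrPlan = data.frame(unit_len = 112L, copies = 3L,
                          palindrome_span = 26L,
                          palindrome_mismatches = 2L,
                          unit_divergence = 3),
      seed = 7)
    .fixtures$small <- c(makeGenome(spec), list(spec = spec))
  }
  .fixtures$small
}

fixtureShaped <- function() {
  if (is.null(.fixtures$shaped)) {
    spec <- paperShapedSpec(seed = 11, lengthBp = 62000, nOrfs = 50)
    .fixtures$shaped <- c(makeGenome(spec), list(spec = spec))
  }
  .fixtures$shaped
}

orfKey <- function(df) paste(df$start, df$end, df$strand)
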