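# Kimura 2-parameter distances on marker-gene alignments and the
# baculovirus species-demarcation rule (polh / lef-8 / lef-9, 0.05
# substitutions/site).

#' Global pairwise alignment of two marker-gene sequences
#'
#' End-to-end affine-gap alignment (Needleman-Wunsch) with the scoring
#' used throughout the package for nucleotide markers: match +5,
#' mismatch -4, gap of length k costs `gapOpen + k * gapExtend`.
#' Alignment is delegated to [Biostrings::pairwiseAlignment()]; its
#' tie-breaking is deterministic.
#'
#' @param a,b DNA strings (nonempty).
#' @param match,mismatch,gapOpen,gapExtend scoring parameters
#'   (defaults 5, -4, 10, 0.5).
#' @param sourceGene marker label stored on the pair (`"polh"`,
#'   `"lef8"`, `"lef9"`, `"other"`).
#' @return an `AlignedPair`: list with gapped `seq_a`, `seq_b` of equal
#'   length, `score`, `source_gene` and the scoring parameters.
#' @examples
#' globalAlignPair("ACGT", "ACGT")$score  # 20
#' @export
globalAlignPair <- function(a, b, match = 5, mismatch = -4, gapOpen = 10,
                            gapExtend = 0.5, sourceGene = "other") {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  submat <- .nucSubMatrix(match, mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = submat,
    gapOpening = gapOpen, gapExtension = gapExtend)
  structure(list(
    seq_a = as.character(Biostrings::alignedPattern(pa)),
    seq_b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa), source_gene = sourceGene,
    params = c(match = match, mismatch = mismatch, gapOpen = gapOpen,
               gapExtend = gapExtend)),
    class = "AlignedPair")
}

.nucSubMatrix <- function(match, mismatch) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- mismatch; m[, "N"] <- mismatch   # N never rewarded
  m
}

#' @export
print.AlignedPair <- function(x, ...) {
  cat(sprintf("AlignedPair (%s): %d columns, score %.1f\n",
              x$source_gene, nchar(x$seq_a), x$score))
  invisible(x)
}

.PURINE <- c("A", "G")

#' Kimura 2-parameter distance of an aligned pair
#'
#' Sites with a gap or N in either sequence are excluded (pairwise
#' deletion; gaps are treated as missing data).  Over the remaining
#' `n` sites, `P` is the proportion of transitions (A<->G, C<->T) and
#' `Q` the proportion of transversions; the distance is
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`, assuming uniform
#' substitution rates among sites.  The result is undefined
#' (saturated) when `1 - 2P - Q <= 0` or `1 - 2Q <= 0`, and an error is
#' signalled when no sites remain.
#'
#' @param pair an `AlignedPair` from [globalAlignPair()], or any list
#'   with gapped `seq_a`/`seq_b` of equal length.
#' @return a [K2PResult-class].
#' @examples
#' p <- globalAlignPair("ACGTACGT", "ACGTACGT")
#' k2pDistance(p)
#' @export
k2pDistance <- function(pair) {
  a <- strsplit(toupper(pair$seq_a), "")[[1L]]
  b <- strsplit(toupper(pair$seq_b), "")[[1L]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0L) stop("no comparable sites after gap/N exclusion")
  diff <- a != b
  ts <- diff & ((a %in% .PURINE) == (b %in% .PURINE))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- w1 > 0 && w2 > 0
  d <- if (defined) -0.5 * log(w1 * sqrt(w2)) else NA_real_
  if (defined && d == 0) d <- 0            # normalize -0
  new("K2PResult", P = P, Q = Q, nSites = as.integer(n),
      distance = d, defined = defined)
}

#' Species demarcation from marker-gene K2P distances
#'
#' Applies the baculovirus demarcation rule: an isolate is a new
#' species when the K2P distances of its polh/lef-8/lef-9 markers to
#' the closest relative all exceed `threshold` (0.05
#' substitutions/site); `not_novel` when all are at or below it, and
#' `inconclusive` for mixed or undefined results.
#'
#' @param results named list or vector mapping marker names to
#'   [K2PResult-class] objects or numeric distances.  At least one of
#'   `polh`, `lef8`, `lef9` must be present.
#' @param threshold demarcation bound (default 0.05 substitutions/site).
#' @return list with `verdict` (`"novel"`, `"not_novel"`,
#'   `"inconclusive"`), the numeric `distances` used, and
#'   `missing_markers`.
#' @examples
#' demarcateSpecies(list(polh = 0.31, lef8 = 0.28, lef9 = 0.25))$verdict
#' @export
demarcateSpecies <- function(results, threshold = 0.05) {
  if (!length(results)) stop("no marker results supplied")
  markers <- c("polh", "lef8", "lef9")
  if (!any(markers %in% names(results)))
    stop("need at least one of: ", paste(markers, collapse = ", "))
  d <- vapply(results, function(x) {
    if (is(x, "K2PResult")) { if (x@defined) x@distance else NA_real_ }
    else as.numeric(x)
  }, numeric(1))
  usable <- d[!is.na(d)]
  verdict <- if (!length(usable)) "inconclusive"
    else if (any(is.na(d))) "inconclusive"
    else if (all(usable > threshold)) "novel"
    else if (all(usable <= threshold)) "not_novel"
    else "inconclusive"
  list(verdict = verdict, distances = d,
       missing_markers = setdiff(markers, names(results)))
}

#' All-pairs K2P distance matrix for one marker gene
#'
#' Aligns every sequence pair globally ([globalAlignPair()]) and
#' computes K2P distances; the matrix is symmetric with a zero
#' diagonal.  Undefined (saturated) pairs are `NA`.
#'
#' @param seqs named character vector (or
#'   [Biostrings::DNAStringSet]) of one marker gene across taxa,
#'   length >= 2.
#' @param sourceGene marker label.
#' @param ... scoring parameters forwarded to [globalAlignPair()].
#' @return numeric distance matrix with a `"results"` attribute
#'   holding the [K2PResult-class] per pair (named `"i|j"`).
#' @export
k2pDistanceMatrix <- function(seqs, sourceGene = "other", ...) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  results <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    pair <- globalAlignPair(seqs[[i]], seqs[[j]],
                            sourceGene = sourceGene, ...)
    r <- k2pDistance(pair)
    D[i, j] <- D[j, i] <- if (r@defined) r@distance else NA_real_
    results[[paste(nm[i], nm[j], sep = "|")]] <- r
  }
  attr(D, "results") <- results
  D
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param D square numeric matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePhylipMatrix <- function(D, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste0(formatC(substr(rownames(D)[i], 1L, 10L),
                              width = -10),
                      paste(sprintf("%9.6f", D[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}
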