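# Internal circular-coordinate arithmetic and fast byte-level sequence
# helpers shared across modules.  Coordinates are 1-based inclusive
# throughout (GenBank convention); origin-spanning spans are encoded as
# end < start and are only legal on circular genomes.

.wrapPos <- function(p, L) ((p - 1L) %% L) + 1L

.spanLength <- function(start, end, L) {
  ifelse(end >= start, end - start + 1L, L - start + 1L + end)
}

.spanPositions <- function(start, end, L) {
  if (end >= start) seq.int(start, end)
  else c(seq.int(start, L), seq.int(1L, end))
}

# decompose a circular span into 1 or 2 linear intervals (matrix cols a, b)
.spanIntervals <- function(s, e, L) {
  if (e >= s) matrix(c(s, e), 1L)
  else matrix(c(s, L, 1L, e), 2L, byrow = TRUE)
}

.spanOverlapLength <- function(s1, e1, s2, e2, L) {
  i1 <- .spanIntervals(s1, e1, L); i2 <- .spanIntervals(s2, e2, L)
  tot <- 0L
  for (a in seq_len(nrow(i1))) for (b in seq_len(nrow(i2)))
    tot <- tot + max(0L, min(i1[a, 2L], i2[b, 2L]) -
                         max(i1[a, 1L], i2[b, 1L]) + 1L)
  tot
}

# TRUE if circular span (s1,e1) contains span (s2,e2) entirely
.spanContains <- function(s1, e1, s2, e2, L) {
  .spanOverlapLength(s1, e1, s2, e2, L) == .spanLength(s2, e2, L)
}

.revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# -- byte-level encoding: A=0 C=1 G=2 T=3 N/other=4 ------------------------

.DNA_CODE <- local({
  v <- rep(4L, 256L)
  v[utf8ToInt("A") + 1L] <- 0L
  v[utf8ToInt("C") + 1L] <- 1L
  v[utf8ToInt("G") + 1L] <- 2L
  v[utf8ToInt("T") + 1L] <- 3L
  v
})

.encodeDNA <- function(x) .DNA_CODE[as.integer(charToRaw(x)) + 1L]

.DECODE <- c("A", "C", "G", "T", "N")

.decodeDNA <- function(code) paste(.DECODE[code + 1L], collapse = "")

# complement of coded bases; N stays N
.COMP_CODE <- c(3L, 2L, 1L, 0L, 4L)

.revcompCode <- function(code) rev(.COMP_CODE[code + 1L])

# codon index = 25*b1 + 5*b2 + b3 over the 5-letter code; any codon
# containing N gets an index involving code 4 and never equals a real codon
.codonIndex <- function(code, starts) {
  25L * code[starts] + 5L * code[starts + 1L] + code[starts + 2L]
}

.CODON_IDX <- function(codon) {
  b <- .encodeDNA(codon)
  25L * b[1L] + 5L * b[2L] + b[3L]
}

.STOP_IDX <- vapply(c("TAA", "TAG", "TGA"), .CODON_IDX, integer(1))
.ATG_IDX <- .CODON_IDX("ATG")

.gcOf <- function(code) {
  acgt <- sum(code < 4L)
  if (acgt == 0L) return(NA_real_)
  100 * sum(code == 1L | code == 2L) / acgt
}

#' G+C content of a genome
#'
#' Percentage of G+C among unambiguous bases (N and other ambiguity
#' codes are excluded from both numerator and denominator), computed on
#' the plus strand.
#'
#' @param genome a [CircularGenome-class] or character DNA string.
#' @return G+C percentage.
#' @examples
#' gcPercent(CircularGenome("ATGC"))
#' @export
gcPercent <- function(genome) {
  s <- if (is(genome, "CircularGenome")) as.character(genomeSeq(genome))
       else toupper(genome)
  .gcOf(.encodeDNA(s))
}
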