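# Comparative genomics: exact local protein alignment, reciprocal best
# hits, gene parity plots, core-gene presence, whole-genome identity,
# and core-gene supermatrix export.
#
# Homology search is exact Smith-Waterman + RBH rather than heuristic
# seeded search: baculovirus proteomes hold ~150 proteins, so all-vs-
# all optimal alignment is tractable and removes E-value/database-size
# dependence.

.asAAStringSet <- function(x) {
  if (is(x, "AAStringSet")) x
  else Biostrings::AAStringSet(unlist(x))
}

#' Optimal local protein alignment
#'
#' Smith-Waterman alignment under BLOSUM62 with gap open -11 / extend
#' -1 (a gap of length k costs 11 + k), via
#' [Biostrings::pairwiseAlignment()].  Identity is computed over the
#' aligned columns (including internal gap columns).
#'
#' @param p1,p2 protein strings over the 20-letter alphabet plus X.
#' @return list with `score` and `identity` (percent).
#' @examples
#' localProteinAlign("MKVLH", "MKVLH")$identity  # 100
#' @export
localProteinAlign <- function(p1, p2) {
  if (!nzchar(p1) || !nzchar(p2)) stop("protein sequences must be nonempty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  list(score = Biostrings::score(pa),
       identity = Biostrings::pid(pa, type = "PID1"))
}

# all-vs-all local alignment score matrix (rows = a, cols = b)
.scoreMatrix <- function(a, b) {
  aset <- .asAAStringSet(a); bset <- .asAAStringSet(b)
  out <- matrix(NA_real_, length(aset), length(bset),
                dimnames = list(names(aset), names(bset)))
  for (i in seq_along(aset)) {
    out[i, ] <- Biostrings::pairwiseAlignment(
      bset, aset[[i]], type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  }
  out
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is reported iff b is a's best-scoring local alignment
#' hit and a is b's, with score >= `minScore` and percent identity >=
#' `minIdentity`.  Score ties are broken by identity, then by
#' lexicographic locus tag.
#'
#' @param proteomeA,proteomeB named character vectors (or
#'   [Biostrings::AAStringSet]) of protein sequences.
#' @param minScore minimum raw alignment score (default 70, calibrated so
#'   that shuffled-residue decoy proteomes yield no pairs).
#' @param minIdentity minimum percent identity (default 25).
#' @return data.frame with columns `locus_a`, `locus_b`, `score`,
#'   `identity`.
#' @export
reciprocalBestHits <- function(proteomeA, proteomeB, minScore = 70,
                               minIdentity = 25) {
  aset <- .asAAStringSet(proteomeA); bset <- .asAAStringSet(proteomeB)
  if (!length(aset) || !length(bset)) stop("proteomes must be nonempty")
  if (is.null(names(aset))) names(aset) <- paste0("a", seq_along(aset))
  if (is.null(names(bset))) names(bset) <- paste0("b", seq_along(bset))
  S <- .scoreMatrix(aset, bset)
  bestOf <- function(scores, nms) {
    top <- which(scores == max(scores))
    if (length(top) > 1L) top <- top[order(nms[top])][1L]
    top
  }
  bestB <- vapply(seq_len(nrow(S)), function(i)
    bestOf(S[i, ], colnames(S)), 1L)
  bestA <- vapply(seq_len(ncol(S)), function(j)
    bestOf(S[, j], rownames(S)), 1L)
  rows <- list()
  for (i in seq_len(nrow(S))) {
    j <- bestB[i]
    if (bestA[j] != i) next
    if (S[i, j] < minScore) next
    al <- localProteinAlign(as.character(aset[[i]]), as.character(bset[[j]]))
    if (al$identity < minIdentity) next
    rows[[length(rows) + 1L]] <- data.frame(
      locus_a = names(aset)[i], locus_b = names(bset)[j],
      score = S[i, j], identity = al$identity, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(locus_a = character(), locus_b = character(),
                      score = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene parity points and collinearity
#'
#' Converts homolog pairs into ordinal gene-rank coordinates (the
#' scatter behind a gene parity plot) and computes the Spearman rank
#' correlation of the two gene orders as a collinearity statistic.
#'
#' @param pairs RBH data.frame from [reciprocalBestHits()].
#' @param orderA,orderB locus tags of each genome sorted by start
#'   coordinate from the (rotated) origin.
#' @return list with `points` (data.frame `rank_a`, `rank_b`,
#'   `locus_a`, `locus_b`) and `correlation`.
#' @export
parityPoints <- function(pairs, orderA, orderB) {
  ra <- match(pairs$locus_a, orderA)
  rb <- match(pairs$locus_b, orderB)
  keep <- !is.na(ra) & !is.na(rb)
  pts <- data.frame(rank_a = ra[keep], rank_b = rb[keep],
                    locus_a = pairs$locus_a[keep],
                    locus_b = pairs$locus_b[keep],
                    stringsAsFactors = FALSE)
  corr <- if (nrow(pts) >= 2L)
    stats::cor(pts$rank_a, pts$rank_b, method = "spearman")
  else NA_real_
  list(points = pts, correlation = corr)
}

#' Core-gene presence check
#'
#' For each reference core-gene family, presence means a reciprocal
#' best hit between the query proteome and the family's reference
#' protein.  Baculoviruses share a set of 38 such core genes.
#'
#' @param proteome named character vector of query proteins.
#' @param coreReferences named character vector, one reference protein
#'   per family (names are the family names).
#' @param ... thresholds forwarded to [reciprocalBestHits()].
#' @return list with `table` (data.frame `family`, `present`,
#'   `query_locus`) and `n_present`.
#' @export
coreGeneCheck <- function(proteome, coreReferences, ...) {
  if (!length(coreReferences)) stop("empty core reference set")
  pairs <- reciprocalBestHits(proteome, coreReferences, ...)
  fam <- names(coreReferences)
  hit <- match(fam, pairs$locus_b)
  tab <- data.frame(family = fam, present = !is.na(hit),
                    query_locus = pairs$locus_a[hit],
                    stringsAsFactors = FALSE)
  list(table = tab, n_present = sum(tab$present))
}

#' Whole-genome nucleotide identity
#'
#' End-to-end global alignment of the two plus strands in linear space
#' (divide-and-conquer affine alignment) with match +5, mismatch -4,
#' gap open 16, gap extend 4; identity is the percentage of identical
#' aligned columns over the alignment length.  Genomes should be
#' rotated to a common origin convention (e.g. the polyhedrin ATG)
#' before comparison.
#'
#' @param g1,g2 [CircularGenome-class] objects or DNA strings.
#' @param match,mismatch,gapOpen,gapExtend scoring (stretcher-style
#'   defaults).
#' @return identity percentage, with the alignment `score`, `matches`
#'   and `columns` as attributes.
#' @export
wholeGenomeIdentity <- function(g1, g2, match = 5, mismatch = -4,
                                gapOpen = 16, gapExtend = 4) {
  s1 <- if (is(g1, "CircularGenome")) as.character(genomeSeq(g1))
        else toupper(g1)
  s2 <- if (is(g2, "CircularGenome")) as.character(genomeSeq(g2))
        else toupper(g2)
  res <- .mmAlign(s1, s2, match, mismatch, gapOpen, gapExtend)
  structure(res$identity, score = res$score, matches = res$matches,
            columns = res$columns)
}

#' Concatenate per-family protein alignments into a supermatrix
#'
#' Column-wise concatenation in the given family order, with a
#' partition table (family to column range) for downstream tree
#' software.  Every family alignment must cover the same taxon set.
#'
#' @param alignments named list of aligned families; each a named
#'   character vector (or [Biostrings::AAStringSet]) of equal-length
#'   gapped sequences keyed by taxon.
#' @param fastaPath,partitionPath optional output files (FASTA
#'   supermatrix and RAxML-style partition table).
#' @return list with `supermatrix` (named character vector) and
#'   `partitions` (data.frame `family`, `start`, `end`).
#' @export
concatenateCoreAlignments <- function(alignments, fastaPath = NULL,
                                      partitionPath = NULL) {
  if (!length(alignments)) stop("no alignments supplied")
  alignments <- lapply(alignments, function(a)
    if (is(a, "AAStringSet")) stats::setNames(as.character(a), names(a))
    else a)
  taxa <- sort(names(alignments[[1L]]))
  for (nm in names(alignments)) {
    have <- sort(names(alignments[[nm]]))
    if (!identical(have, taxa)) {
      missing <- setdiff(taxa, have)
      stop("taxon set mismatch in family '", nm, "'; missing: ",
           paste(missing, collapse = ", "))
    }
    if (length(unique(nchar(alignments[[nm]]))) != 1L)
      stop("family '", nm, "' is not a flush alignment")
  }
  widths <- vapply(alignments, function(a) nchar(a[[1L]]), 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  partitions <- data.frame(family = names(alignments),
                           start = as.integer(starts),
                           end = as.integer(ends),
                           stringsAsFactors = FALSE)
  supermatrix <- vapply(taxa, function(tx)
    paste(vapply(alignments, function(a) a[[tx]], ""), collapse = ""),
    character(1))
  if (!is.null(fastaPath))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(supermatrix),
                                fastaPath)
  if (!is.null(partitionPath))
    writeLines(sprintf("PROT, %s = %d-%d", partitions$family,
                       partitions$start, partitions$end), partitionPath)
  list(supermatrix = supermatrix, partitions = partitions)
}
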