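# ORF prediction on circular genomes under baculovirus annotation
# conventions: >= 50 aa, 75 bp overlap rule with a conserved-homolog
# exception, ORFs inside hr loci left unannotated.

# scan one oriented strand; returns oriented-coordinate ORFs
.scanStrand <- function(code, L, circular, minAa, variant) {
  scan <- if (circular) c(code, code, code) else code
  n <- length(scan)
  out <- list()
  for (f in 0:2) {
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    idx <- .codonIndex(scan, starts)
    is_stop <- idx %in% .STOP_IDX
    is_atg <- idx == .ATG_IDX
    stop_pos <- which(is_stop)
    if (!length(stop_pos)) next
    atg_pos <- which(is_atg)
    if (!length(atg_pos)) next
    # segment id = number of stops strictly upstream of the ATG; the
    # reported ATG per segment is the most upstream one ("longest"
    # variant) or the most downstream one ("shortest")
    seg <- findInterval(atg_pos, stop_pos + 0L)
    rep_atg <- if (variant == "longest") !duplicated(seg)
               else !duplicated(seg, fromLast = TRUE)
    a_all <- atg_pos[rep_atg]
    seg_all <- seg[rep_atg]
    has_stop <- seg_all + 1L <= length(stop_pos)
    a_all <- a_all[has_stop]; seg_all <- seg_all[has_stop]
    if (!length(a_all)) next
    sp_all <- stop_pos[seg_all + 1L]
    aa_all <- sp_all - a_all
    p_all <- starts[a_all]
    keep <- aa_all >= minAa
    if (circular) keep <- keep & p_all > L & p_all <= 2L * L &
        3L * (aa_all + 1L) <= L
    for (w in which(keep)) {
      ntlen <- 3L * (aa_all[w] + 1L)
      q <- if (circular) .wrapPos(p_all[w], L) else p_all[w]
      qe <- if (circular) .wrapPos(q + ntlen - 1L, L) else q + ntlen - 1L
      out[[length(out) + 1L]] <- c(q, qe, aa_all[w])
    }
  }
  if (!length(out)) return(matrix(integer(), 0L, 3L))
  unique(do.call(rbind, out))
}

#' Predict open reading frames on a circular genome
#'
#' Scans all six reading frames, treating the genome circularly (ORFs
#' may span the origin; no ORF is double-counted).  Each ORF runs from
#' an ATG to the first in-frame stop; by default the longest variant
#' (most upstream ATG after the previous in-frame stop) is reported.
#' Only ORFs encoding at least `minAa` amino acids (excluding the stop)
#' are returned.
#'
#' @param genome a [CircularGenome-class].
#' @param minAa minimum protein length in amino acids (default 50, the
#'   baculovirus annotation convention).
#' @param variant `"longest"` (most upstream ATG, default) or
#'   `"shortest"` (ATG nearest the stop).
#' @return data.frame with columns `locus_tag` (provisional `orf_NNN`
#'   in ascending start order), `start`, `end`, `strand`, `length_aa`,
#'   `frame` (0-2, of the plus-strand start coordinate), `translation`
#'   and `annotation_class` (`NA` until [classifyOrfs()]).
#' @examples
#' g <- CircularGenome(paste0(
#'   "ATG", strrep("GCT", 60), "TAA", strrep("C", 40)), topology = "linear")
#' findOrfs(g, minAa = 50)
#' @export
findOrfs <- function(genome, minAa = 50, variant = c("longest", "shortest")) {
  variant <- match.arg(variant)
  L <- genomeLength(genome)
  if (L < 3L * (minAa + 1L)) {
    warning("genome shorter than the minimum ORF length; no ORFs")
    return(.orfFrame())
  }
  circ <- isCircular(genome)
  code <- .encodeDNA(as.character(genomeSeq(genome)))
  res <- list()
  plus <- .scanStrand(code, L, circ, minAa, variant)
  if (nrow(plus))
    res[[1L]] <- data.frame(start = plus[, 1L], end = plus[, 2L],
                            strand = "+", length_aa = plus[, 3L],
                            stringsAsFactors = FALSE)
  minus <- .scanStrand(.revcompCode(code), L, circ, minAa, variant)
  if (nrow(minus))
    res[[2L]] <- data.frame(start = L - minus[, 2L] + 1L,
                            end = L - minus[, 1L] + 1L, strand = "-",
                            length_aa = minus[, 3L], stringsAsFactors = FALSE)
  if (!length(res)) return(.orfFrame())
  orfs <- do.call(rbind, res)
  orfs <- orfs[order(orfs$start, orfs$end, orfs$strand), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs$frame <- (orfs$start - 1L) %% 3L
  cds <- vapply(seq_len(nrow(orfs)), function(i)
    extractSubsequence(genome, orfs$start[i], orfs$end[i], orfs$strand[i]),
    character(1))
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                           if.fuzzy.codon = "solve"))
  orfs$translation <- sub("\\*$", "", aa)
  orfs$locus_tag <- sprintf("orf_%03d", seq_len(nrow(orfs)))
  orfs$annotation_class <- NA_character_
  orfs[, c("locus_tag", "start", "end", "strand", "length_aa", "frame",
           "translation", "annotation_class")]
}

.orfFrame <- function() {
  data.frame(locus_tag = character(), start = integer(), end = integer(),
             strand = character(), length_aa = integer(), frame = integer(),
             translation = character(), annotation_class = character(),
             stringsAsFactors = FALSE)
}

.orfNtLength <- function(orfs, L) {
  .spanLength(orfs$start, orfs$end, L)
}

#' Resolve overlapping ORFs (75 bp rule)
#'
#' For every pair of ORFs whose circular plus-strand projections
#' overlap by more than `maxOverlapBp`, only the larger ORF is kept —
#' unless the smaller one is flagged as a conserved baculovirus homolog
#' in `homologHits`.  Pairs overlapping by at most `maxOverlapBp` are
#' both retained.  Input order is preserved; the operation is
#' idempotent.  When two overlapping ORFs are the same length the
#' plus-strand one, then the one with the lower start coordinate, is
#' treated as the larger.
#'
#' @param orfs ORF data.frame from [findOrfs()].
#' @param genomeLengthBp genome length in bp (for circular overlap).
#' @param homologHits character vector of locus tags with a conserved
#'   homolog match (or named logical vector); may be empty.
#' @param maxOverlapBp tolerated overlap (default 75).
#' @return filtered ORF data.frame.
#' @export
resolveOverlaps <- function(orfs, genomeLengthBp, homologHits = character(),
                            maxOverlapBp = 75) {
  n <- nrow(orfs)
  if (n < 2L) return(orfs)
  if (is.logical(homologHits)) homologHits <- names(homologHits)[homologHits]
  L <- as.integer(genomeLengthBp)
  len <- .orfNtLength(orfs, L)
  # preference order: longer first; ties plus-strand then lower start
  pref <- order(-len, orfs$strand != "+", orfs$start)
  rank <- integer(n); rank[pref] <- seq_len(n)
  alive <- rep(TRUE, n)
  for (ii in seq_len(n - 1L)) for (jj in seq.int(ii + 1L, n)) {
    if (!alive[ii] || !alive[jj]) next
    ov <- .spanOverlapLength(orfs$start[ii], orfs$end[ii],
                             orfs$start[jj], orfs$end[jj], L)
    if (ov <= maxOverlapBp) next
    smaller <- if (rank[ii] < rank[jj]) jj else ii
    if (!(orfs$locus_tag[smaller] %in% homologHits))
      alive[smaller] <- FALSE
  }
  out <- orfs[alive, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove ORFs lying entirely inside homologous regions
#'
#' ORFs within hr sequences are left unannotated because of the
#' relative instability of those loci; ORFs that only partially overlap
#' an hr are retained.
#'
#' @param orfs ORF data.frame.
#' @param hrs list of [HrLocus-class] objects (or a data.frame with
#'   `start`/`end` columns).
#' @param genomeLengthBp genome length in bp.
#' @return filtered ORF data.frame.
#' @export
maskHrOrfs <- function(orfs, hrs, genomeLengthBp) {
  if (!length(hrs) || nrow(orfs) == 0L) return(orfs)
  L <- as.integer(genomeLengthBp)
  spans <- if (is.data.frame(hrs)) hrs
           else data.frame(start = vapply(hrs, function(h) h@start, 1L),
                           end = vapply(hrs, function(h) h@end, 1L))
  inside <- vapply(seq_len(nrow(orfs)), function(i)
    any(vapply(seq_len(nrow(spans)), function(j)
      .spanContains(spans$start[j], spans$end[j],
                    orfs$start[i], orfs$end[i], L), TRUE)), TRUE)
  out <- orfs[!inside, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign final locus tags in map order
#'
#' Tags are assigned `<prefix>_NNN` in ascending start coordinate from
#' the (rotated) origin, the naming scheme used on baculovirus physical
#' maps where polyhedrin is ORF1.
#'
#' @param orfs ORF data.frame.
#' @param prefix tag prefix (default `"orf"`).
#' @return ORF data.frame, reordered by start with fresh tags.
#' @export
assignLocusTags <- function(orfs, prefix = "orf") {
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs$locus_tag <- sprintf("%s_%03d", prefix, seq_len(nrow(orfs)))
  orfs
}

#' Headline genome statistics
#'
#' G+C percentage (ambiguous bases excluded from numerator and
#' denominator), ORF counts by orientation, and the percentage of the
#' genome covered by at least one ORF (union of spans, both strands
#' projected onto plus-strand positions).
#'
#' @param genome a [CircularGenome-class].
#' @param orfs ORF data.frame.
#' @return list with `length_bp`, `gc_percent`, `orf_count`,
#'   `forward_count`, `reverse_count`, `coding_fraction_percent`.
#' @export
genomeStats <- function(genome, orfs) {
  L <- genomeLength(genome)
  covered <- logical(L)
  if (nrow(orfs)) for (i in seq_len(nrow(orfs)))
    covered[.spanPositions(orfs$start[i], orfs$end[i], L)] <- TRUE
  list(length_bp = L,
       gc_percent = gcPercent(genome),
       orf_count = nrow(orfs),
       forward_count = sum(orfs$strand == "+"),
       reverse_count = sum(orfs$strand == "-"),
       coding_fraction_percent = 100 * sum(covered) / L)
}

#' Classify ORFs against reference protein sets
#'
#' Assigns each ORF the highest-priority annotation class (core >
#' conserved > common > unique) for which a reciprocal-best-hit match
#' to the corresponding reference protein collection exists.  ORFs with
#' no match in any set are `unique`.
#'
#' @param orfs ORF data.frame with translations.
#' @param referenceSets named list with any of the elements `core`,
#'   `conserved`, `common`; each a named character vector (or
#'   [Biostrings::AAStringSet]) of reference protein sequences.
#' @param minScore,minIdentity RBH acceptance thresholds passed to
#'   [reciprocalBestHits()].
#' @return `orfs` with `annotation_class` filled and an
#'   `is_homolog_of` column naming the matched reference.
#' @export
classifyOrfs <- function(orfs, referenceSets, minScore = 70,
                         minIdentity = 25) {
  orfs$annotation_class <- "unique"
  orfs$is_homolog_of <- NA_character_
  referenceSets <- referenceSets[lengths(referenceSets) > 0L]
  if (!length(referenceSets)) {
    warning("empty reference sets: all ORFs classified 'unique'")
    return(orfs)
  }
  proteome <- stats::setNames(orfs$translation, orfs$locus_tag)
  for (cls in intersect(c("common", "conserved", "core"),
                        names(referenceSets))) {
    refs <- referenceSets[[cls]]
    if (is(refs, "AAStringSet")) refs <- as.character(refs)
    pairs <- reciprocalBestHits(proteome, refs, minScore = minScore,
                                minIdentity = minIdentity)
    hit <- match(orfs$locus_tag, pairs$locus_a)
    found <- !is.na(hit)
    orfs$annotation_class[found] <- cls
    orfs$is_homolog_of[found] <- pairs$locus_b[hit[found]]
  }
  orfs
}
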