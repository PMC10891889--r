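# Early/late promoter motif classification of 180-nt upstream windows.
#
# Early evidence: TATAW with a CAKT mRNA-start motif 25-35 nt downstream
# (start-to-start, boundary inclusive), or a TATA-like TAATWAA element.
# Late evidence: DTAAG.  Motifs are scanned on the coding strand only;
# positions are signed offsets with -1 the base immediately 5' of the A
# of the ATG.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

.PROMOTER_MOTIFS <- c(tata = "TATAW", cakt = "CAKT", tata_like = "TAATWAA",
                      late = "DTAAG")

#' Extract the upstream window of an ORF
#'
#' Returns the `window`-nt region immediately 5' of the initiation
#' codon, on the ORF's coding strand, wrapping circularly.  On circular
#' genomes the window is capped at `genome length - ORF length` so it
#' never runs into the ORF itself; on linear genomes it is truncated at
#' the sequence boundary with a warning.
#'
#' @param genome a [CircularGenome-class].
#' @param orf one ORF (single-row data.frame or list with `start`,
#'   `end`, `strand`).
#' @param window window size in nt (default 180).
#' @return character DNA string (its last base sits at offset -1).
#' @export
upstreamWindow <- function(genome, orf, window = 180) {
  L <- genomeLength(genome)
  start <- as.integer(orf$start); end <- as.integer(orf$end)
  strand <- as.character(orf$strand)
  ntlen <- .spanLength(start, end, L)
  if (isCircular(genome)) {
    w <- min(window, L - ntlen)
    if (w <= 0L) return("")
    if (strand == "+") {
      extractSubsequence(genome, .wrapPos(start - w, L),
                         .wrapPos(start - 1L, L), "+")
    } else {
      extractSubsequence(genome, .wrapPos(end + 1L, L),
                         .wrapPos(end + w, L), "-")
    }
  } else {
    if (strand == "+") {
      from <- start - window
      if (from < 1L) {
        warning("window truncated at the sequence start")
        from <- 1L
      }
      if (start == 1L) return("")
      extractSubsequence(genome, from, start - 1L, "+")
    } else {
      to <- end + window
      if (to > L) {
        warning("window truncated at the sequence end")
        to <- L
      }
      if (end == L) return("")
      extractSubsequence(genome, end + 1L, to, "-")
    }
  }
}

#' Scan a window for an IUPAC motif
#'
#' Reports all (possibly overlapping) match start positions of the
#' degenerate `motif` in `window`, as signed offsets (-1 = the base
#' immediately 5' of the ATG, i.e. the last base of the window).
#' Ambiguity codes are honoured in the motif only; an N in the window
#' never matches.
#'
#' @param window DNA string (the upstream window).
#' @param motif IUPAC pattern, e.g. `"DTAAG"`.
#' @return integer vector of signed offsets of the motif's first base.
#' @examples
#' scanMotif("CCTATAACC", "TATAW")
#' @export
scanMotif <- function(window, motif) {
  motif <- toupper(motif)
  letters <- strsplit(motif, "")[[1L]]
  if (!all(letters %in% names(.IUPAC_SETS)))
    stop("invalid IUPAC letter in motif: ", motif)
  wlen <- nchar(window)
  m <- length(letters)
  if (wlen < m || m == 0L) return(integer())
  code <- .encodeDNA(toupper(window))
  starts <- seq_len(wlen - m + 1L)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(m)) {
    allowed <- logical(5L)   # A C G T N; N never matches
    allowed[match(.IUPAC_SETS[[letters[j]]], .DECODE)] <- TRUE
    ok <- ok & allowed[code[starts + j - 1L] + 1L]
  }
  which(ok) - wlen - 1L
}

#' Classify one upstream window
#'
#' Early evidence is a TATAW motif with a CAKT motif 25-35 nt
#' downstream (start-to-start, boundaries inclusive) or a TAATWAA
#' element; late evidence is any DTAAG.  The classification is
#' `"early"`, `"late"`, `"both"` or `"none"` accordingly.
#'
#' @param window DNA string from [upstreamWindow()].
#' @param locus_tag optional tag stored on the call.
#' @param spacingMin,spacingMax allowed TATA-to-CAKT spacing (nt).
#' @return a `PromoterCall`: list with `locus_tag`, `classification`,
#'   `early_hits` (data.frame `tata_pos`, `cakt_pos`, `spacing`),
#'   `tata_like_hits`, `late_hits`.
#' @examples
#' w <- paste0(strrep("C", 100), "TATAA", strrep("C", 28), "CATT",
#'             strrep("C", 43))
#' classifyPromoter(w)$classification
#' @export
classifyPromoter <- function(window, locus_tag = NA_character_,
                             spacingMin = 25, spacingMax = 35) {
  tata <- scanMotif(window, .PROMOTER_MOTIFS[["tata"]])
  cakt <- scanMotif(window, .PROMOTER_MOTIFS[["cakt"]])
  taat <- scanMotif(window, .PROMOTER_MOTIFS[["tata_like"]])
  late <- scanMotif(window, .PROMOTER_MOTIFS[["late"]])
  pairs <- expand.grid(tata_pos = tata, cakt_pos = cakt)
  pairs$spacing <- pairs$cakt_pos - pairs$tata_pos
  pairs <- pairs[pairs$spacing >= spacingMin & pairs$spacing <= spacingMax, ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  has_early <- nrow(pairs) > 0L || length(taat) > 0L
  has_late <- length(late) > 0L
  classification <- if (has_early && has_late) "both"
                    else if (has_early) "early"
                    else if (has_late) "late" else "none"
  structure(list(locus_tag = locus_tag, classification = classification,
                 early_hits = pairs, tata_like_hits = taat,
                 late_hits = late),
            class = "PromoterCall")
}

#' @export
print.PromoterCall <- function(x, ...) {
  cat(sprintf("PromoterCall%s: %s (%d TATAW/CAKT pair(s), %d TAATWAA, %d DTAAG)\n",
              if (is.na(x$locus_tag)) "" else paste0(" ", x$locus_tag),
              x$classification, nrow(x$early_hits),
              length(x$tata_like_hits), length(x$late_hits)))
  invisible(x)
}

#' Classify the upstream windows of a set of ORFs
#'
#' @param genome a [CircularGenome-class].
#' @param orfs ORF data.frame.
#' @param loci optional character vector restricting the scan to these
#'   locus tags (the promoter census of a genome report is often
#'   restricted, e.g. to the unique genes).
#' @param window window size (default 180).
#' @return list of `PromoterCall` objects, named by locus tag.
#' @export
scanPromoters <- function(genome, orfs, loci = NULL, window = 180) {
  if (!is.null(loci)) orfs <- orfs[orfs$locus_tag %in% loci, , drop = FALSE]
  calls <- lapply(seq_len(nrow(orfs)), function(i)
    classifyPromoter(upstreamWindow(genome, orfs[i, ], window),
                     locus_tag = orfs$locus_tag[i]))
  stats::setNames(calls, orfs$locus_tag)
}

#' Summarize promoter calls
#'
#' Counts per class, the mean TATA-to-CAKT spacing over early evidence
#' and the mean signed DTAAG offset over late ORFs.  One representative
#' motif per ORF enters the averages: the TATAW/CAKT pair whose TATA
#' lies closest to the start codon, and the DTAAG closest to the start
#' codon.
#'
#' @param calls list of `PromoterCall` objects.
#' @return list with `n`, `counts` (named early/late/both/none),
#'   `mean_spacing` and `mean_late_offset` (`NA` when no ORF
#'   contributes).
#' @export
promoterSummary <- function(calls) {
  if (!length(calls)) stop("no promoter calls supplied")
  cls <- vapply(calls, `[[`, "", "classification")
  counts <- vapply(c("early", "late", "both", "none"),
                   function(k) sum(cls == k), 0L)
  spacings <- unlist(lapply(calls, function(x) {
    if (!x$classification %in% c("early", "both")) return(NULL)
    if (!nrow(x$early_hits)) return(NULL)     # TAATWAA-only early call
    best <- x$early_hits[which.max(x$early_hits$tata_pos), ]
    best$spacing[which.max(best$cakt_pos)]
  }))
  offsets <- unlist(lapply(calls, function(x) {
    if (!x$classification %in% c("late", "both")) return(NULL)
    max(x$late_hits)
  }))
  list(n = length(calls), counts = counts,
       mean_spacing = if (length(spacings)) mean(spacings) else NA_real_,
       mean_late_offset = if (length(offsets)) mean(offsets) else NA_real_)
}
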