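# De novo detection of homologous regions (hrs): tandem repeat arrays
# of ~50-250 bp units carrying an imperfect palindromic core near the
# unit center.
#
# The repeat finder estimates candidate periods from the distances
# between exact k-mer re-occurrences (k = 12, packed exactly into 24
# bits so there are no hash collisions), then refines array boundaries
# by an exhaustive phase search: every offset of the unit frame over
# the candidate region is decomposed into consecutive units, a
# majority-vote consensus is built, and the phase maximizing the run of
# units above the identity floor wins.

#' Find tandem repeat arrays
#'
#' Detects maximal tandem arrays with unit length (period) inside
#' `[minPeriod, maxPeriod]`.  Candidate periods come from spaced exact
#' k-mer matches; boundaries and the unit frame are refined against the
#' majority-vote consensus.  Overlapping candidates are merged keeping
#' the higher copy-number call.
#'
#' @param seq DNA string or [CircularGenome-class] (scanned on the plus
#'   strand, linearly).
#' @param minPeriod,maxPeriod unit-length search band in bp (defaults
#'   50-250, bracketing the ~112 bp units of alphabaculovirus hrs).
#' @param minCopies minimum copy number (default 2).
#' @param minIdentity minimum percent identity of a unit to the
#'   consensus (default 70).
#' @param k k-mer size for period estimation (default 12).
#' @param minVotes minimum number of concordant k-mer distance votes
#'   for a candidate region (default 6; a random 10 kb sequence
#'   produces on the order of 0.1 votes in total, so the null yields no
#'   arrays).
#' @return list of arrays; each a list with `start`, `end`, `period`,
#'   `copies`, `unit_starts`, `consensus`, `identities` (percent, one
#'   per unit) and `mean_identity`.
#' @export
findTandemRepeats <- function(seq, minPeriod = 50, maxPeriod = 250,
                              minCopies = 2, minIdentity = 70,
                              k = 12, minVotes = 6) {
  s <- if (is(seq, "CircularGenome")) as.character(genomeSeq(seq))
       else toupper(seq)
  code <- .encodeDNA(s)
  n <- length(code)
  if (n < 2L * minPeriod) stop("sequence shorter than 2 * minPeriod")
  m <- n - k + 1L
  val <- integer(m); bad <- integer(m)
  for (j in 0:(k - 1L)) {
    cj <- code[(1L + j):(m + j)]
    val <- val + cj %% 4L * 4L^j
    bad <- bad + (cj == 4L)
  }
  ok <- which(bad == 0L)
  if (!length(ok)) return(list())
  ord <- ok[order(val[ok], ok)]
  v <- val[ord]
  same <- c(FALSE, v[-1L] == v[-length(v)])
  d <- c(NA_integer_, diff(ord))
  keep <- same & !is.na(d) & d >= minPeriod & d <= maxPeriod
  votes <- data.frame(pos = ord[keep] - d[keep], period = d[keep])
  if (nrow(votes) < minVotes) return(list())
  votes <- votes[order(votes$pos), , drop = FALSE]
  brk <- c(0L, which(diff(votes$pos) > maxPeriod), nrow(votes))
  arrays <- list()
  for (ci in seq_len(length(brk) - 1L)) {
    cl <- votes[(brk[ci] + 1L):brk[ci + 1L], , drop = FALSE]
    if (nrow(cl) < minVotes) next
    p <- as.integer(round(stats::median(cl$period)))
    # generous margins: k-mer votes can start/stop well inside the
    # terminal units when those units carry mutations
    a <- max(1L, min(cl$pos) - p - 30L)
    b <- min(n, max(cl$pos) + k - 1L + 2L * p + 30L)
    arr <- .refineArray(code, a, b, p, minIdentity, minCopies)
    if (!is.null(arr)) arrays[[length(arrays) + 1L]] <- arr
  }
  .mergeArrays(arrays)
}

.majorityConsensus <- function(M) {
  # M: period x units matrix of base codes; ties -> smallest code
  counts <- vapply(0:3, function(bcode) rowSums(M == bcode),
                   numeric(nrow(M)))
  max.col(counts, ties.method = "first") - 1L
}

.refineArray <- function(code, a, b, p, minIdentity, minCopies) {
  # Phase search: for every offset of the unit frame, segment the
  # region by the identity of ADJACENT unit pairs (robust to the
  # background units flanking the array, which would contaminate a
  # region-wide consensus), keep the longest run of concordant units,
  # and score phases by run length then total pair identity.
  best <- NULL
  for (phi in 0:(p - 1L)) {
    starts <- seq.int(a + phi, b - p + 1L, by = p)
    if (length(starts) < 2L) next
    M <- matrix(code[outer(0:(p - 1L), starts, `+`)], nrow = p)
    m <- ncol(M)
    adj <- 100 * colMeans(M[, -m, drop = FALSE] == M[, -1L, drop = FALSE])
    good <- adj >= minIdentity
    r <- rle(good)
    if (!any(r$values)) next
    runs <- which(r$values)
    lens <- r$lengths[runs]
    ends <- cumsum(r$lengths)[runs]
    bi <- which.max(lens)
    p0 <- ends[bi] - lens[bi] + 1L; p1 <- ends[bi]   # pair indices
    score <- c(lens[bi] + 1L, sum(adj[p0:p1]))
    if (is.null(best) || score[1L] > best$score[1L] ||
        (score[1L] == best$score[1L] && score[2L] > best$score[2L])) {
      best <- list(starts = starts[p0:(p1 + 1L)], score = score)
    }
  }
  if (is.null(best) || length(best$starts) < ceiling(minCopies)) return(NULL)
  ustarts <- best$starts
  M <- matrix(code[outer(0:(p - 1L), ustarts, `+`)], nrow = p)
  cons <- .majorityConsensus(M)
  ident <- 100 * colMeans(M == cons)
  list(start = ustarts[1L], end = ustarts[length(ustarts)] + p - 1L,
       period = p, copies = length(ustarts), unit_starts = ustarts,
       consensus = .decodeDNA(cons), identities = ident,
       mean_identity = mean(ident))
}

.mergeArrays <- function(arrays) {
  if (length(arrays) < 2L) return(arrays)
  ord <- order(vapply(arrays, function(a) as.numeric(a$start), 1))
  arrays <- arrays[ord]
  out <- list(arrays[[1L]])
  for (i in seq_along(arrays)[-1L]) {
    prev <- out[[length(out)]]; cur <- arrays[[i]]
    if (cur$start <= prev$end) {
      # overlap: keep the higher copy number, then higher identity
      keepCur <- cur$copies > prev$copies ||
        (cur$copies == prev$copies && cur$mean_identity > prev$mean_identity)
      if (keepCur) out[[length(out)]] <- cur
    } else out[[length(out) + 1L]] <- cur
  }
  out
}

#' Find (imperfect) palindromes
#'
#' Reports maximal inverted repeats: for every center (left-arm end
#' position and loop gap up to `maxGap`) the arms are extended as far
#' as the bounds and the mismatch budget allow; the result is reported
#' when the arm reaches `minArm`.  A mismatch is a pair of positions
#' where the left-arm base does not equal the complement of the
#' mirrored right-arm base; N never matches.  Results are sorted by
#' span (2*arm + gap) descending.
#'
#' @param seq DNA string.
#' @param minArm minimum arm length (default 10).
#' @param maxGap maximum loop between the arms (default 8).
#' @param maxMismatch maximum mismatching arm pairs (default 3).
#' @return data.frame with columns `start`, `end`, `center`, `armLen`,
#'   `gap`, `mismatches`, `span`.
#' @examples
#' findPalindromes("AAAATTTT", minArm = 4, maxGap = 0, maxMismatch = 0)
#' @export
findPalindromes <- function(seq, minArm = 10, maxGap = 8, maxMismatch = 3) {
  code <- .encodeDNA(toupper(seq))
  n <- length(code)
  res <- list()
  for (g in 0:maxGap) {
    jcap <- pmin(seq_len(n), n - g - seq_len(n))   # max arm per left end l
    ls <- which(jcap >= minArm)
    if (!length(ls)) next
    mism <- integer(length(ls))
    arm <- integer(length(ls))
    armMism <- integer(length(ls))
    alive <- rep(TRUE, length(ls))
    maxJ <- max(jcap[ls])
    for (j in seq_len(maxJ)) {
      idx <- which(alive & jcap[ls] >= j)
      if (!length(idx)) break
      l <- ls[idx]
      left <- code[l - j + 1L]
      right <- code[l + g + j]
      match <- left < 4L & right < 4L & left == .COMP_CODE[right + 1L]
      mism[idx] <- mism[idx] + !match
      over <- mism[idx] > maxMismatch
      alive[idx[over]] <- FALSE
      oki <- idx[!over]
      arm[oki] <- j
      armMism[oki] <- mism[oki]
    }
    hit <- which(arm >= minArm)
    if (length(hit)) {
      l <- ls[hit]
      res[[length(res) + 1L]] <- data.frame(
        start = l - arm[hit] + 1L, end = l + g + arm[hit],
        armLen = arm[hit], gap = g, mismatches = armMism[hit])
    }
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      center = numeric(), armLen = integer(),
                      gap = integer(), mismatches = integer(),
                      span = integer()))
  df <- do.call(rbind, res)
  df$span <- 2L * df$armLen + df$gap
  df$center <- (df$start + df$end) / 2
  df <- df[order(-df$span, df$start, df$gap),
           c("start", "end", "center", "armLen", "gap", "mismatches",
             "span")]
  rownames(df) <- NULL
  df
}

#' Assemble hr loci from tandem arrays
#'
#' A tandem array becomes an hr locus iff its unit consensus contains a
#' palindrome (per [findPalindromes()]) whose center lies in the
#' central third of the unit.  Loci are named `hr1`, `hr2`, ... in
#' genome order.  A+T richness is recorded but never used as a filter.
#'
#' @param arrays output of [findTandemRepeats()].
#' @param genome the [CircularGenome-class] the arrays were found on.
#' @param minArm,maxGap,maxMismatch palindrome search parameters
#'   (defaults admit the ~26 bp imperfect cores of alphabaculovirus
#'   hrs).
#' @return list of [HrLocus-class] objects.
#' @export
assembleHrs <- function(arrays, genome, minArm = 10, maxGap = 8,
                        maxMismatch = 3) {
  s <- as.character(genomeSeq(genome))
  out <- list()
  for (arr in arrays) {
    if (arr$copies < 2L) next
    u <- nchar(arr$consensus)
    pal <- findPalindromes(arr$consensus, minArm = minArm, maxGap = maxGap,
                           maxMismatch = maxMismatch)
    if (!nrow(pal)) next
    central <- pal$center >= u / 3 & pal$center <= 2 * u / 3
    if (!any(central)) next
    best <- pal[central, ][1L, ]   # largest span (already sorted)
    units <- data.frame(
      start = arr$unit_starts,
      end = arr$unit_starts + arr$period - 1L,
      sequence = substring(s, arr$unit_starts,
                           arr$unit_starts + arr$period - 1L),
      identity = arr$identities, stringsAsFactors = FALSE)
    span_seq <- substr(s, arr$start, arr$end)
    at <- 100 - .gcOf(.encodeDNA(span_seq))
    out[[length(out) + 1L]] <- new("HrLocus",
      name = "hr", start = as.integer(arr$start), end = as.integer(arr$end),
      units = units, consensus = arr$consensus,
      palindrome = list(start = best$start, end = best$end,
                        center = best$center, armLen = best$armLen,
                        gap = best$gap, mismatches = best$mismatches,
                        span = best$span),
      atPercent = at)
  }
  if (!length(out)) return(out)
  ord <- order(vapply(out, function(h) h@start, 1L))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]@name <- paste0("hr", i)
  out
}

#' Report hr loci with their flanking ORFs
#'
#' Names the nearest upstream and downstream locus tags for each hr
#' (computed circularly) and carries the unit alignment as a list
#' column.
#'
#' @param hrs list of [HrLocus-class].
#' @param orfs annotated ORF data.frame.
#' @param genomeLengthBp genome length (for circular flank distances).
#' @return data.frame, one row per hr, with a `units` list column of
#'   aligned unit sequences.
#' @export
hrReport <- function(hrs, orfs, genomeLengthBp) {
  L <- as.integer(genomeLengthBp)
  rows <- lapply(hrs, function(h) {
    updist <- (h@start - orfs$end - 1L) %% L
    dndist <- (orfs$start - h@end - 1L) %% L
    data.frame(
      name = h@name, start = h@start, end = h@end,
      n_units = nrow(h@units), unit_length = nchar(h@consensus),
      at_percent = h@atPercent,
      palindrome_span = h@palindrome$span,
      palindrome_mismatches = h@palindrome$mismatches,
      upstream_orf = if (nrow(orfs)) orfs$locus_tag[which.min(updist)]
                     else NA_character_,
      downstream_orf = if (nrow(orfs)) orfs$locus_tag[which.min(dndist)]
                       else NA_character_,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(data.frame())
  df$units <- lapply(hrs, function(h) h@units$sequence)
  df
}

#' Write hr loci as BED
#'
#' BED uses 0-based half-open coordinates; the internal 1-based
#' inclusive spans are converted on output.
#'
#' @param hrs list of [HrLocus-class].
#' @param genome the genome (for the chromosome name).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHrBed <- function(hrs, genome, path) {
  lines <- vapply(hrs, function(h)
    sprintf("%s\t%d\t%d\t%s", genomeId(genome), h@start - 1L, h@end,
            h@name), character(1))
  writeLines(lines, path)
  invisible(path)
}
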