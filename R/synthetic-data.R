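# Seeded synthetic baculovirus-like genomes with recorded ground
# truth, so every pipeline stage can be validated without downloads.
#
# Background sequence is i.i.d. at the requested G+C.  ORFs are planted
# as [TAA][ATG ... stop] cassettes (the leading in-frame stop pins the
# most-upstream-ATG rule to the planted start).  Promoter-bearing ORFs
# receive a clear >= 200 bp upstream zone whose 180-nt window is
# scrubbed to the exact planted motif content; hr loci are planted as
# tandem units with a centered imperfect palindrome whose mismatch
# count is exact (per-unit divergence is applied outside the
# palindrome).  A scrub loop removes spurious ORFs so that planted ORF
# coordinates are recovered with exact precision and recall.
#
# Three pseudo-random streams (layout, sequence, mutation/scrub) are
# derived from the seed so adding a feature category does not shift
# other draws.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.randDNA <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((100 - gc) / 2, (100 - gc) / 2, gc / 2, gc / 2) / 100)
}

# aa-1 interior codons free of in-frame stops, drawn at the target GC
.interiorCodons <- function(aa, gc) {
  if (aa <= 1L) return(character(0))
  chars <- .randDNA(3L * (aa - 1L), gc)
  cod <- matrix(chars, nrow = 3L)
  repeat {
    codstr <- apply(cod, 2L, paste, collapse = "")
    bad <- which(codstr %in% .STOP_CODONS)
    if (!length(bad)) break
    cod[, bad] <- .randDNA(3L * length(bad), gc)
  }
  as.vector(cod)
}

#' Specify a synthetic genome
#'
#' @param lengthBp total genome length in bp.
#' @param gcPercent background G+C percentage (default 45, the
#'   alphabaculovirus neighbourhood).
#' @param orfPlan data.frame with columns `length_aa`, `strand`
#'   (`"+"`/`"-"`) and `promoter_class` (`"early"`, `"late"`,
#'   `"both"`, `"none"`, or `NA` for no promoter truth).
#' @param hrPlan data.frame with columns `unit_len`, `copies`,
#'   `palindrome_span`, `palindrome_mismatches`, `unit_divergence`
#'   (percent).
#' @param seed integer seed; fully determines [makeGenome()] output.
#' @return a `GenomeSpec` list.
#' @export
genomeSpec <- function(lengthBp, gcPercent = 45, orfPlan = NULL,
                       hrPlan = NULL, seed = 1) {
  if (is.null(orfPlan))
    orfPlan <- data.frame(length_aa = integer(), strand = character(),
                          promoter_class = character(),
                          stringsAsFactors = FALSE)
  if (is.null(hrPlan))
    hrPlan <- data.frame(unit_len = integer(), copies = integer(),
                         palindrome_span = integer(),
                         palindrome_mismatches = integer(),
                         unit_divergence = numeric())
  structure(list(lengthBp = as.integer(lengthBp), gcPercent = gcPercent,
                 orfPlan = orfPlan, hrPlan = hrPlan,
                 seed = as.integer(seed)),
            class = "GenomeSpec")
}

#' A study-shaped genome specification
#'
#' Emulates the architecture of a group II alphabaculovirus genome:
#' ~45% G+C, densely packed ORFs of >= 50 aa on both strands (~55%
#' forward), three hr loci of 4/3/2 copies of ~112 bp units with a
#' 26 bp imperfect palindromic core, and a 17-locus promoter census
#' (3 early, 8 late, 2 both, 4 none).
#'
#' @param seed integer seed.
#' @param lengthBp genome length (default 160000; sized so ~83% is
#'   coding).
#' @param nOrfs number of planted ORFs (default 140).
#' @return a `GenomeSpec`.
#' @export
paperShapedSpec <- function(seed = 1, lengthBp = 160000, nOrfs = 140) {
  set.seed(seed * 1000003L %% 2147483647L)
  aa <- sample(60:550, nOrfs, replace = TRUE)
  # keep the packing feasible: scale down until cassettes + junctions fit
  overhead <- 17L * 450L + nOrfs * 50L + 3L * 600L + 2000L
  repeat {
    if (sum(3L * aa + 6L) + overhead <= lengthBp) break
    aa <- pmax(60L, floor(aa * 0.95))
  }
  strand <- sample(c("+", "-"), nOrfs, replace = TRUE,
                   prob = c(0.553, 0.447))
  pc <- rep(NA_character_, nOrfs)
  census <- c(rep("early", 3), rep("late", 8), rep("both", 2),
              rep("none", 4))
  idx <- sort(sample(seq_len(nOrfs), length(census)))
  pc[idx] <- sample(census)
  genomeSpec(
    lengthBp = lengthBp, gcPercent = 45,
    orfPlan = data.frame(length_aa = aa, strand = strand,
                         promoter_class = pc, stringsAsFactors = FALSE),
    hrPlan = data.frame(unit_len = 112L, copies = c(4L, 3L, 2L),
                        palindrome_span = 26L, palindrome_mismatches = 2L,
                        unit_divergence = 3),
    seed = seed)
}

# build one hr cassette; returns list(chars, truth)
.buildHr <- function(unit_len, copies, pal_span, pal_mm, divergence, gc) {
  gap <- 2L - pal_span %% 2L
  arm <- (pal_span - gap) %/% 2L
  hr_gc <- min(gc, 35)                      # hrs are AT-rich
  unit <- .randDNA(unit_len, hr_gc)
  left <- .randDNA(arm, hr_gc)
  right <- rev(c(A = "T", C = "G", G = "C", T = "A")[left])
  if (pal_mm > 0L) {
    mmpos <- sample(seq_len(arm), pal_mm)
    for (p in mmpos) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")[left[arm - p + 1L]]
      right[p] <- sample(setdiff(c("A", "C", "G", "T"), comp), 1L)
    }
  }
  pal <- c(left, if (gap > 0L) .randDNA(gap, hr_gc), right)
  pstart <- (unit_len - pal_span) %/% 2L + 1L
  unit[pstart:(pstart + pal_span - 1L)] <- pal
  chars <- character(0)
  outside <- setdiff(seq_len(unit_len), pstart:(pstart + pal_span - 1L))
  for (k in seq_len(copies)) {
    u <- unit
    nmut <- round(divergence / 100 * length(outside))
    if (k > 1L && nmut > 0L) {
      mpos <- sample(outside, nmut)
      for (p in mpos)
        u[p] <- sample(setdiff(c("A", "C", "G", "T"), u[p]), 1L)
    }
    chars <- c(chars, u)
  }
  list(chars = chars,
       truth = list(unit_len = unit_len, copies = copies,
                    palindrome_start = pstart,
                    palindrome_end = pstart + pal_span - 1L,
                    palindrome_span = pal_span,
                    palindrome_mismatches = pal_mm))
}

.COMPL <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcompChars <- function(x) unname(rev(.COMPL[x]))

#' Generate a synthetic genome with ground truth
#'
#' See the package vignette for the construction.  The same spec and
#' seed always produce byte-identical output.
#'
#' @param spec a `GenomeSpec` from [genomeSpec()] or
#'   [paperShapedSpec()].
#' @param maxScrubRounds iteration cap for the spurious-ORF/motif
#'   scrub loop.
#' @param minAa the ORF-calling floor the truth is scrubbed against
#'   (default 50).
#' @return list with `genome` (a [CircularGenome-class]) and `truth`
#'   (list with `orfs`, `promoters`, `hrs` data.frames).
#' @export
makeGenome <- function(spec, maxScrubRounds = 40, minAa = 50) {
  stopifnot(inherits(spec, "GenomeSpec"))
  L <- spec$lengthBp
  gc <- spec$gcPercent
  plan <- spec$orfPlan
  hrPlan <- spec$hrPlan
  n <- nrow(plan)
  nHr <- nrow(hrPlan)

  ## ---- stream 1: layout ------------------------------------------------
  set.seed(spec$seed * 3L %% 2147483647L)
  hasP <- !is.na(plan$promoter_class)
  # junction i sits before ORF i; a trailing junction n+1 closes the map
  dl <- c(FALSE, (plan$strand == "-" & hasP))          # length n+1
  dr <- c((plan$strand == "+" & hasP), FALSE)
  lw <- ifelse(dl, 200L, 0L)
  rw <- ifelse(dr, 200L, 0L)
  hrAt <- integer(0)
  if (nHr > 0L) {
    hrAt <- if (n > 0L) pmax(2L, pmin(n, round(n * seq_len(nHr) / (nHr + 1L))))
            else rep(1L, nHr)
    if (anyDuplicated(hrAt)) hrAt <- seq_len(nHr) + 1L
  }
  hrLen <- if (nHr) hrPlan$unit_len * hrPlan$copies else integer(0)
  mids <- sample(8:40, n + 1L, replace = TRUE)
  if (nHr) mids[hrAt] <- mids[hrAt] + 60L + hrLen
  cassLen <- if (n) 3L * plan$length_aa + 6L else integer(0)
  minTotal <- sum(lw) + sum(rw) + sum(mids) + sum(cassLen)
  if (minTotal > L)
    stop("infeasible packing: need ", minTotal, " bp but lengthBp is ", L)
  extra <- L - minTotal
  add <- rep(extra %/% (n + 1L), n + 1L)
  add[n + 1L] <- add[n + 1L] + extra %% (n + 1L)
  mids <- mids + add

  # absolute coordinates
  zone <- integer(L)  # 0 free, 1 cassette, 2 hr, 3 planted motif, 4 window
  orf_truth <- vector("list", n)
  hr_truth <- vector("list", nHr)
  hrSeen <- 0L
  cur <- 1L
  cassStart <- integer(n)
  hrStart <- integer(nHr)
  for (i in seq_len(n + 1L)) {
    cur <- cur + lw[i]
    if (nHr && i %in% hrAt) {
      k <- which(hrAt == i)
      hrStart[k] <- cur + 30L
    }
    cur <- cur + mids[i]
    cur <- cur + rw[i]
    if (i <= n) {
      cassStart[i] <- cur
      cur <- cur + cassLen[i]
    }
  }
  stopifnot(cur - 1L <= L)

  ## ---- stream 2: sequence ---------------------------------------------
  set.seed(spec$seed * 3L %% 2147483647L + 1L)
  chars <- .randDNA(L, gc)
  for (i in seq_len(n)) {
    aa <- plan$length_aa[i]
    cass <- c("T", "A", "A",            # in-frame stop pinning the start
              "A", "T", "G",
              .interiorCodons(aa, gc),
              strsplit(sample(.STOP_CODONS, 1L), "")[[1L]])
    s <- cassStart[i]; e <- s + cassLen[i] - 1L
    if (plan$strand[i] == "+") {
      chars[s:e] <- cass
      orf_start <- s + 3L; orf_end <- e
    } else {
      chars[s:e] <- .revcompChars(cass)
      orf_start <- s; orf_end <- e - 3L
    }
    zone[s:e] <- 1L
    orf_truth[[i]] <- data.frame(
      locus = sprintf("planted_%03d", i), start = orf_start,
      end = orf_end, strand = plan$strand[i], length_aa = aa,
      promoter_class = plan$promoter_class[i], stringsAsFactors = FALSE)
  }
  for (k in seq_len(nHr)) {
    hb <- .buildHr(hrPlan$unit_len[k], hrPlan$copies[k],
                   hrPlan$palindrome_span[k],
                   hrPlan$palindrome_mismatches[k],
                   hrPlan$unit_divergence[k], gc)
    s <- hrStart[k]; e <- s + length(hb$chars) - 1L
    chars[s:e] <- hb$chars
    zone[s:e] <- 2L
    hr_truth[[k]] <- data.frame(
      name = sprintf("hr%d", k), start = s, end = e,
      unit_len = hb$truth$unit_len, copies = hb$truth$copies,
      palindrome_span = hb$truth$palindrome_span,
      palindrome_mismatches = hb$truth$palindrome_mismatches,
      stringsAsFactors = FALSE)
  }

  orfs <- if (n) do.call(rbind, orf_truth) else
    data.frame(locus = character(), start = integer(), end = integer(),
               strand = character(), length_aa = integer(),
               promoter_class = character(), stringsAsFactors = FALSE)

  # promoter windows: mark zone 4 (background reserved for a window)
  winOf <- function(i) {
    if (orfs$strand[i] == "+") {
      atg <- orfs$start[i]
      c(.wrapPos(atg - 180L, L), .wrapPos(atg - 1L, L))
    } else {
      c(.wrapPos(orfs$end[i] + 1L, L), .wrapPos(orfs$end[i] + 180L, L))
    }
  }
  pIdx <- which(!is.na(orfs$promoter_class))
  for (i in pIdx) {
    w <- winOf(i)
    pos <- .spanPositions(w[1L], w[2L], L)
    zone[pos[zone[pos] == 0L]] <- 4L
  }

  ## ---- stream 3: motifs + scrub ---------------------------------------
  set.seed(spec$seed * 3L %% 2147483647L + 2L)
  # window offset -> plus position (offset -1 adjacent to the ATG)
  offToPlus <- function(i, off) {
    as.integer(if (orfs$strand[i] == "+") .wrapPos(orfs$start[i] + off, L)
               else .wrapPos(orfs$end[i] - off, L))
  }
  writeMotif <- function(i, off, motif) {
    mchars <- strsplit(motif, "")[[1L]]
    len <- length(mchars)
    if (orfs$strand[i] == "+") {
      pos <- vapply(0:(len - 1L), function(d) offToPlus(i, off + d), 1L)
      chars[pos] <<- mchars
    } else {
      pos <- vapply(0:(len - 1L), function(d) offToPlus(i, off + d), 1L)
      chars[pos] <<- .COMPL[mchars]
    }
    zone[pos] <<- 3L
    pos
  }
  prom_truth <- list()
  for (i in pIdx) {
    cls <- orfs$promoter_class[i]
    tata_off <- NA_integer_; cakt_off <- NA_integer_
    dtaag_off <- NA_integer_; spacing <- NA_integer_
    # choose all offsets first; for "both", redraw until a DTAAG slot
    # disjoint from the TATA/CAKT pair exists (always true for TATA at
    # -75 or above)
    repeat {
      if (cls %in% c("early", "both")) {
        tata_off <- sample(-90:-50, 1L)
        spacing <- sample(25:35, 1L)
        cakt_off <- tata_off + spacing
      }
      if (!cls %in% c("late", "both")) break
      cand <- -80:-40
      if (!is.na(tata_off))
        cand <- cand[cand + 4L < tata_off | cand > cakt_off + 3L]
      if (length(cand)) {
        dtaag_off <- if (length(cand) == 1L) cand else sample(cand, 1L)
        break
      }
    }
    if (cls %in% c("early", "both")) {
      writeMotif(i, tata_off, paste0("TATA", sample(c("A", "T"), 1L)))
      writeMotif(i, cakt_off, paste0("CA", sample(c("G", "T"), 1L), "T"))
    }
    if (cls %in% c("late", "both"))
      writeMotif(i, dtaag_off, paste0(sample(c("A", "G", "T"), 1L), "TAAG"))
    prom_truth[[length(prom_truth) + 1L]] <- data.frame(
      locus = orfs$locus[i], class = cls, tata_off = tata_off,
      cakt_off = cakt_off, spacing = spacing, dtaag_off = dtaag_off,
      stringsAsFactors = FALSE)
  }
  promoters <- if (length(prom_truth)) do.call(rbind, prom_truth) else
    data.frame(locus = character(), class = character(),
               tata_off = integer(), cakt_off = integer(),
               spacing = integer(), dtaag_off = integer(),
               stringsAsFactors = FALSE)

  ## scrub loop: exact motif truth in windows, no spurious ORFs
  unwanted <- list(early = "DTAAG", late = c("TATAW", "TAATWAA"),
                   none = c("TATAW", "TAATWAA", "DTAAG", "CAKT"),
                   both = character(0))
  hrSpans <- if (nHr) do.call(rbind, hr_truth) else NULL
  insideHr <- function(s, e) {
    if (is.null(hrSpans)) return(FALSE)
    any(vapply(seq_len(nrow(hrSpans)), function(j)
      .spanContains(hrSpans$start[j], hrSpans$end[j], s, e, L), TRUE))
  }
  truthKey <- paste(orfs$start, orfs$end, orfs$strand)

  for (round in seq_len(maxScrubRounds)) {
    changed <- FALSE
    genome <- CircularGenome(paste(chars, collapse = ""), id = "synthetic",
                             topology = "circular")
    # (a) stray motifs inside promoter windows
    for (i in pIdx) {
      cls <- orfs$promoter_class[i]
      w <- upstreamWindow(genome, orfs[i, c("start", "end", "strand")], 180L)
      for (motif in unwanted[[cls]]) {
        for (hit in scanMotif(w, motif)) {
          span <- hit + 0:(nchar(motif) - 1L)
          pos <- vapply(span, function(o) offToPlus(i, o), 1L)
          free <- pos[zone[pos] %in% c(0L, 4L)]
          if (!length(free)) next
          p <- if (length(free) == 1L) free else sample(free, 1L)
          if (isTRUE(getOption("baculoscribe.debug")))
            message("  motif scrub write at ", p, " (zone ", zone[p],
                    ", locus ", orfs$locus[i], ", motif ", motif, ")")
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
          changed <- TRUE
        }
      }
    }
    if (changed) {
      genome <- CircularGenome(paste(chars, collapse = ""),
                               id = "synthetic", topology = "circular")
    }
    # (b) spurious ORFs
    found <- findOrfs(genome, minAa = minAa)
    foundKey <- paste(found$start, found$end, found$strand)
    spurious <- found[!(foundKey %in% truthKey), , drop = FALSE]
    if (nrow(spurious)) {
      spurious <- spurious[!vapply(seq_len(nrow(spurious)), function(r)
        insideHr(spurious$start[r], spurious$end[r]), TRUE), , drop = FALSE]
    }
    if (isTRUE(getOption("baculoscribe.debug")))
      message("scrub round ", round, ": ", nrow(spurious),
              " spurious ORFs, motif changes: ", changed)
    if (nrow(spurious) == 0L && !changed) break
    for (r in seq_len(nrow(spurious))) {
      if (.killSpuriousOrf(spurious[r, ], orfs, L, environment()))
        changed <- TRUE
      else if (isTRUE(getOption("baculoscribe.debug")))
        message("  could not kill spurious ORF at ",
                spurious$start[r], "..", spurious$end[r], " ",
                spurious$strand[r])
    }
  }
  genome <- CircularGenome(paste(chars, collapse = ""), id = "synthetic",
                           topology = "circular")
  found <- findOrfs(genome, minAa = minAa)
  foundKey <- paste(found$start, found$end, found$strand)
  spurious <- found[!(foundKey %in% truthKey), , drop = FALSE]
  if (nrow(spurious)) {
    keep <- vapply(seq_len(nrow(spurious)), function(r)
      insideHr(spurious$start[r], spurious$end[r]), TRUE)
    if (any(!keep))
      warning("scrub loop left ", sum(!keep), " spurious ORF(s)")
  }
  if (!all(truthKey %in% foundKey)) {
    miss <- orfs[!(truthKey %in% foundKey), , drop = FALSE]
    stop("internal error: planted ORF(s) lost during scrubbing: ",
         paste(sprintf("%s %d..%d%s", miss$locus, miss$start, miss$end,
                       miss$strand), collapse = ", "))
  }

  list(genome = genome,
       truth = list(orfs = orfs, promoters = promoters,
                    hrs = if (nHr) do.call(rbind, hr_truth) else NULL))
}

# Destroy one spurious ORF by mutating `env$chars` in place.
# `span` below is kept in the ORF's 5'->3' order: for a minus-strand
# feature the plus positions run backwards, and the oriented character
# at step j is the complement of chars[span[j]].
.killSpuriousOrf <- function(orf, plantedOrfs, L, env) {
  span <- .spanPositions(orf$start, orf$end, L)
  if (orf$strand == "-") span <- rev(span)
  ncod <- length(span) %/% 3L
  # overwriting the terminal stop codon would be a no-op; targeting the
  # ATG or any interior codon destroys the ORF
  codStarts <- seq.int(1L, by = 3L, length.out = ncod - 1L)
  writeOriented <- function(positions, orientedChars, strand) {
    env$chars[positions] <- if (strand == "-") .COMPL[orientedChars]
                            else orientedChars
  }
  # prefer wholly free codons (zone 0), then window background (zone 4)
  for (zset in list(0L, c(0L, 4L))) {
    freeCod <- codStarts[vapply(codStarts, function(cs)
      all(env$zone[span[cs:(cs + 2L)]] %in% zset), TRUE)]
    if (length(freeCod)) {
      cs <- if (length(freeCod) == 1L) freeCod else sample(freeCod, 1L)
      stopc <- strsplit(sample(.STOP_CODONS, 1L), "")[[1L]]
      writeOriented(span[cs:(cs + 2L)], stopc, orf$strand)
      return(TRUE)
    }
  }
  # overlap with a planted host ORF: swap an interior host sense codon
  # so that the spurious frame reads a stop at the overlap
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")),
                         1L, paste, collapse = ""), .STOP_CODONS)
  spuriousCodon <- function(chars, sc) {
    spos <- span[(3L * sc - 2L):(3L * sc)]
    if (orf$strand == "-") paste(.COMPL[chars[spos]], collapse = "")
    else paste(chars[spos], collapse = "")
  }
  for (h in seq_len(nrow(plantedOrfs))) {
    ho <- plantedOrfs[h, ]
    hspan <- .spanPositions(ho$start, ho$end, L)
    if (ho$strand == "-") hspan <- rev(hspan)
    common <- intersect(hspan, span)
    if (!length(common)) next
    hcod <- seq.int(1L, by = 3L, length.out = length(hspan) %/% 3L)
    # interior codons only: never touch the host's ATG or stop codon
    hcod <- hcod[hcod >= 4L & hcod <= length(hspan) - 5L]
    hcod <- hcod[vapply(hcod, function(cs)
      any(hspan[cs:(cs + 2L)] %in% common), TRUE)]
    if (!length(hcod)) next
    hcodTry <- if (length(hcod) == 1L) hcod
               else sample(hcod, min(8L, length(hcod)))
    for (cs in hcodTry) {
      hpos <- hspan[cs:(cs + 2L)]
      saved <- env$chars[hpos]
      sp_cod <- unique((match(hpos, span) - 1L) %/% 3L + 1L)
      sp_cod <- sp_cod[!is.na(sp_cod) & sp_cod >= 1L & sp_cod < ncod]
      if (!length(sp_cod)) next
      for (cand in sample(sense, min(24L, length(sense)))) {
        writeOriented(hpos, strsplit(cand, "")[[1L]], ho$strand)
        if (any(vapply(sp_cod, function(sc)
          spuriousCodon(env$chars, sc) %in% .STOP_CODONS, TRUE)))
          return(TRUE)
        env$chars[hpos] <- saved
      }
    }
  }
  FALSE
}

#' Evolve a sequence under the Kimura 2-parameter process
#'
#' Applies substitutions site-independently with the exact K80
#' transition probabilities at divergence `targetDistance`
#' (substitutions/site), so the expected K2P distance estimate of the
#' input/output pair equals `targetDistance`.  The
#' transition:transversion rate ratio is `tsTvRatio` (kappa = alpha /
#' beta); no indels are introduced.
#'
#' @param seq DNA string.
#' @param targetDistance expected substitutions/site, in `[0, 1]`.
#' @param tsTvRatio kappa (default 2).
#' @param seed integer seed.
#' @return mutated DNA string of the same length.
#' @export
evolveSequence <- function(seq, targetDistance, tsTvRatio = 2.0, seed = 1) {
  stopifnot(targetDistance >= 0, targetDistance <= 1)
  if (targetDistance == 0) return(seq)
  set.seed(as.integer(seed))
  kappa <- tsTvRatio
  bt <- targetDistance / (kappa + 2)
  at <- targetDistance * kappa / (kappa + 2)
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt)        # each of the two transversions
  chars <- strsplit(toupper(seq), "")[[1L]]
  u <- stats::runif(length(chars))
  TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
  TRANSVERSION <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
  isb <- chars %in% c("A", "C", "G", "T")
  ts_hit <- isb & u < p_ts
  tv1 <- isb & u >= p_ts & u < p_ts + p_tv
  tv2 <- isb & u >= p_ts + p_tv & u < p_ts + 2 * p_tv
  chars[ts_hit] <- TRANSITION[chars[ts_hit]]
  chars[tv1] <- vapply(chars[tv1], function(b) TRANSVERSION[[b]][1L], "")
  chars[tv2] <- vapply(chars[tv2], function(b) TRANSVERSION[[b]][2L], "")
  paste(chars, collapse = "")
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Generate a pair of proteomes with known orthology
#'
#' Each of `nGenes` random proteins is copied into the second proteome
#' with residues mutated to approximately `identityPercent` identity;
#' `nDecoys` unrelated proteins are appended to each side.  The true
#' pairing is returned for validating [reciprocalBestHits()].
#'
#' @param nGenes number of ortholog pairs (>= 1).
#' @param identityPercent target percent identity of each pair.
#' @param nDecoys unrelated decoy proteins per proteome (default 0).
#' @param seed integer seed.
#' @param lenRange protein length range (default 120-400 aa).
#' @return list with `proteomeA`, `proteomeB` (named character
#'   vectors) and `truth` (data.frame `locus_a`, `locus_b`).
#' @export
makeOrthologPair <- function(nGenes, identityPercent = 60, nDecoys = 0,
                             seed = 1, lenRange = c(120, 400)) {
  stopifnot(nGenes >= 1)
  set.seed(as.integer(seed))
  randProt <- function(len) paste(sample(.AA20, len, TRUE), collapse = "")
  lens <- sample(lenRange[1L]:lenRange[2L], nGenes, replace = TRUE)
  pa <- vapply(lens, randProt, "")
  pb <- vapply(seq_len(nGenes), function(i) {
    chars <- strsplit(pa[i], "")[[1L]]
    nmut <- round((1 - identityPercent / 100) * length(chars))
    if (nmut > 0L) {
      pos <- sample(seq_along(chars), nmut)
      chars[pos] <- vapply(chars[pos], function(a)
        sample(setdiff(.AA20, a), 1L), "")
    }
    paste(chars, collapse = "")
  }, "")
  names(pa) <- sprintf("gA_%03d", seq_len(nGenes))
  names(pb) <- sprintf("gB_%03d", seq_len(nGenes))
  truth <- data.frame(locus_a = names(pa), locus_b = names(pb),
                      stringsAsFactors = FALSE)
  if (nDecoys > 0L) {
    dl <- sample(lenRange[1L]:lenRange[2L], 2L * nDecoys, replace = TRUE)
    da <- stats::setNames(vapply(dl[seq_len(nDecoys)], randProt, ""),
                          sprintf("decoyA_%03d", seq_len(nDecoys)))
    db <- stats::setNames(
      vapply(dl[nDecoys + seq_len(nDecoys)], randProt, ""),
      sprintf("decoyB_%03d", seq_len(nDecoys)))
    pa <- c(pa, da); pb <- c(pb, db)
  }
  list(proteomeA = pa, proteomeB = pb, truth = truth)
}
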