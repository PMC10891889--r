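# Genome and annotation I/O plus circular-coordinate sequence access.
#
# Coordinates are 1-based inclusive (GenBank convention).  A feature
# with end < start spans the origin of a circular genome; in GenBank
# output such a feature is written as join(start..L,1..end), in GFF3 it
# is split into two parts sharing an ID.

.FEATURE_COLS <- c("locus_tag", "start", "end", "strand", "kind")

#' Build a feature table
#'
#' @param locus_tag character vector of locus tags.
#' @param start,end 1-based inclusive coordinates (integer vectors);
#'   `end < start` encodes an origin-spanning feature on a circular
#'   genome.
#' @param strand `"+"` or `"-"`.
#' @param kind one of `"CDS"`, `"hr"`, `"repeat"`, `"other"`.
#' @param qualifiers optional list (one named character vector per
#'   feature) of extra qualifiers.
#' @return data.frame with columns `locus_tag`, `start`, `end`,
#'   `strand`, `kind` and a `qualifiers` list column.
#' @examples
#' featureTable("orf1", 1L, 9L, "+", "CDS")
#' @export
featureTable <- function(locus_tag = character(), start = integer(),
                         end = integer(), strand = character(),
                         kind = character(), qualifiers = NULL) {
  n <- length(locus_tag)
  if (is.null(qualifiers)) qualifiers <- rep(list(character()), n)
  df <- data.frame(locus_tag = as.character(locus_tag),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), kind = as.character(kind),
                   stringsAsFactors = FALSE)
  df$qualifiers <- qualifiers
  df
}

#' Validate a feature table against a genome
#'
#' Checks coordinate bounds, strand and kind values, and that
#' origin-spanning features (end < start) only occur on circular
#' genomes.
#'
#' @param features feature data.frame (see [featureTable()]).
#' @param genome a [CircularGenome-class].
#' @return the feature table, invisibly; errors on violation.
#' @export
validateFeatures <- function(features, genome) {
  L <- genomeLength(genome)
  if (nrow(features)) {
    if (any(features$start < 1L | features$start > L |
            features$end < 1L | features$end > L))
      stop("feature coordinates out of bounds [1, ", L, "]")
    if (!isCircular(genome) && any(features$end < features$start))
      stop("origin-spanning features require a circular genome")
    if (!all(features$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (!all(features$kind %in% c("CDS", "hr", "repeat", "other")))
      stop("kind must be one of CDS, hr, repeat, other")
  }
  invisible(features)
}

#' Read a genome (and its annotation) from FASTA or GenBank
#'
#' Reads the first sequence record of the file.  GenBank `CDS` and
#' `repeat_region` features are converted to the package's feature
#' table; FASTA yields an empty feature table.  Topology is taken from
#' the GenBank LOCUS line when present, otherwise from `topology`.
#'
#' @param path input file.
#' @param format `"auto"` (default; sniffed from content), `"fasta"` or
#'   `"genbank"`.
#' @param topology fallback topology when the format does not carry one.
#' @return list with elements `genome` ([CircularGenome-class]) and
#'   `features` (data.frame).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">g", "ATGAAATAA"), f)
#' readGenome(f)$genome
#' @export
readGenome <- function(path, format = c("auto", "fasta", "genbank"),
                       topology = "circular") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty input file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(first, ">")) "fasta"
              else if (length(first) && grepl("^LOCUS", first)) "genbank"
              else stop("cannot determine format of ", path)
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readDNAStringSet(path),
                    error = function(e) stop("unparseable FASTA: ",
                                             conditionMessage(e)))
    if (length(set) == 0L) stop("no sequence records in ", path)
    id <- sub("\\s.*", "", names(set)[1L])
    g <- CircularGenome(as.character(set[[1L]]), id = id,
                        topology = topology)
    list(genome = g, features = featureTable())
  } else {
    .readGenbank(path, topology)
  }
}

.parseGbLocation <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  loc <- gsub("complement\\(|join\\(|\\)|<|>", "", loc)
  parts <- strsplit(loc, ",")[[1L]]
  nums <- lapply(parts, function(p) as.integer(strsplit(p, "\\.\\.")[[1L]]))
  first <- nums[[1L]]; last <- nums[[length(nums)]]
  c(start = first[1L], end = last[length(last)], strand = strand)
}

.readGenbank <- function(path, topology) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("unparseable GenBank file (no LOCUS line)")
  topo <- if (grepl("circular", locus[1L])) "circular"
          else if (grepl("linear", locus[1L])) "linear" else topology
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]

  ori <- grep("^ORIGIN", lines)
  endrec <- grep("^//", lines)
  if (!length(ori)) stop("unparseable GenBank file (no ORIGIN)")
  to <- if (length(endrec)) endrec[1L] - 1L else length(lines)
  seqtxt <- toupper(gsub("[^A-Za-z]", "",
                         paste(lines[(ori[1L] + 1L):to], collapse = "")))
  if (!nzchar(seqtxt)) stop("empty sequence in GenBank record")
  if (grepl("[^ACGTNRYSWKMBDHV]", seqtxt))
    stop("non-DNA alphabet in GenBank record")

  feat_from <- grep("^FEATURES", lines)
  tags <- character(); starts <- integer(); ends <- integer()
  strands <- character(); kinds <- character(); quals <- list()
  if (length(feat_from)) {
    block <- lines[(feat_from[1L] + 1L):(ori[1L] - 1L)]
    i <- 1L
    while (i <= length(block)) {
      ln <- block[i]
      if (grepl("^ {5}\\S", ln)) {
        key <- trimws(substr(ln, 1L, 20L))
        loc <- trimws(substr(ln, 21L, nchar(ln)))
        i <- i + 1L
        # location continuation lines
        while (i <= length(block) && grepl("^ {21}", block[i]) &&
               !grepl("^ {21}/", block[i])) {
          loc <- paste0(loc, trimws(block[i])); i <- i + 1L
        }
        q <- character()
        while (i <= length(block) && grepl("^ {21}/", block[i])) {
          qline <- trimws(sub("^ {21}/", "", block[i]))
          i <- i + 1L
          while (i <= length(block) && grepl("^ {21}", block[i]) &&
                 !grepl("^ {21}/", block[i]) && !grepl("^ {5}\\S", block[i])) {
            qline <- paste(qline, trimws(block[i])); i <- i + 1L
          }
          kv <- strsplit(qline, "=", fixed = TRUE)[[1L]]
          val <- if (length(kv) > 1L)
            gsub("^\"|\"$", "", paste(kv[-1L], collapse = "=")) else ""
          q[kv[1L]] <- val
        }
        if (key %in% c("CDS", "repeat_region", "misc_feature")) {
          pl <- .parseGbLocation(loc)
          kind <- switch(key,
            CDS = "CDS",
            repeat_region = if (identical(unname(q["note"]), "hr")) "hr"
                            else "repeat",
            misc_feature = "other")
          tags <- c(tags, if (!is.na(q["locus_tag"])) unname(q["locus_tag"])
                          else paste0("feat_", length(tags) + 1L))
          starts <- c(starts, pl[["start"]]); ends <- c(ends, pl[["end"]])
          strands <- c(strands, pl[["strand"]]); kinds <- c(kinds, kind)
          quals <- c(quals, list(q[setdiff(names(q), "locus_tag")]))
        }
      } else i <- i + 1L
    }
  }
  g <- CircularGenome(seqtxt, id = id, topology = topo)
  feats <- featureTable(tags, starts, ends, strands, kinds, quals)
  list(genome = g, features = feats)
}

#' Extract a (possibly origin-spanning) subsequence
#'
#' Returns the 1-based inclusive span `start..end`.  When `end < start`
#' and the genome is circular, the span wraps through the origin.
#' Strand `"-"` returns the reverse complement of the plus-strand span.
#'
#' @param genome a [CircularGenome-class].
#' @param start,end coordinates in `[1, length]`.
#' @param strand `"+"` or `"-"`.
#' @return character DNA string.
#' @examples
#' g <- CircularGenome("ATGCATGC")
#' extractSubsequence(g, 7, 2)        # wraps: "GCAT"
#' extractSubsequence(g, 1, 4, "-")   # revcomp: "GCAT"
#' @export
extractSubsequence <- function(genome, start, end, strand = "+") {
  L <- genomeLength(genome)
  if (start < 1L || start > L || end < 1L || end > L)
    stop("coordinates must lie in [1, ", L, "]")
  s <- as.character(genomeSeq(genome))
  if (end >= start) {
    out <- substr(s, start, end)
  } else {
    if (!isCircular(genome))
      stop("span wraps the origin but the genome is linear")
    out <- paste0(substr(s, start, L), substr(s, 1L, end))
  }
  if (strand == "-") out <- .revcompChr(out)
  out
}

#' Rotate a circular genome to a new origin
#'
#' Returns a genome whose sequence begins at `position` of the input —
#' the operation used to place the polyhedrin ATG at the top of the
#' physical map.  Length and base composition are unchanged.
#'
#' @param genome a circular [CircularGenome-class].
#' @param position new origin, `1 <= position <= length`.
#' @param originNote note to store on the result.
#' @return rotated [CircularGenome-class].
#' @examples
#' rotateToOrigin(CircularGenome("AACGTT"), 4)
#' @export
rotateToOrigin <- function(genome, position,
                           originNote = genome@originNote) {
  if (!isCircular(genome)) stop("cannot rotate a linear genome")
  L <- genomeLength(genome)
  if (position < 1L || position > L) stop("position out of range")
  s <- as.character(genomeSeq(genome))
  rot <- if (position == 1L) s
         else paste0(substr(s, position, L), substr(s, 1L, position - 1L))
  CircularGenome(rot, id = genomeId(genome), topology = "circular",
                 originNote = originNote)
}

# map a coordinate of the unrotated genome into the rotated frame
.rotateCoord <- function(pos, position, L) .wrapPos(pos - position + 1L, L)

#' Write an annotation (and genome) to GenBank, GFF3 or TSV
#'
#' Round-trip safe: reading the written GenBank with [readGenome()], or
#' the written GFF3/TSV with [readFeatures()], reproduces coordinates,
#' strands and locus tags exactly.  Origin-spanning features are written
#' as `join(start..L,1..end)` in GenBank and as two `part`-tagged lines
#' sharing an `ID` in GFF3.
#'
#' @param genome a [CircularGenome-class].
#' @param features feature data.frame (validated against `genome`).
#' @param path output file.
#' @param format `"genbank"`, `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(genome, features, path,
                            format = c("genbank", "gff3", "tsv")) {
  format <- match.arg(format)
  validateFeatures(features, genome)
  switch(format,
    genbank = .writeGenbank(genome, features, path),
    gff3 = .writeGff3(genome, features, path),
    tsv = .writeTsv(features, path))
  invisible(path)
}

.writeGenbank <- function(genome, features, path) {
  L <- genomeLength(genome)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf(
    "LOCUS       %-16s %d bp    DNA     %-8s VRL 01-JAN-2026",
    genomeId(genome), L, topology(genome)), con)
  writeLines(c(sprintf("DEFINITION  %s.", genomeId(genome)),
               "FEATURES             Location/Qualifiers",
               sprintf("     source          1..%d", L)), con)
  if (nrow(features)) for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    loc <- if (f$end >= f$start) sprintf("%d..%d", f$start, f$end)
           else sprintf("join(%d..%d,1..%d)", f$start, L, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    key <- switch(f$kind, CDS = "CDS", hr = "repeat_region",
                  "repeat" = "repeat_region", other = "misc_feature")
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", f$locus_tag),
               con)
    if (f$kind == "hr")
      writeLines("                     /note=\"hr\"", con)
    q <- features$qualifiers[[i]]
    for (k in setdiff(names(q), "note"))
      writeLines(sprintf("                     /%s=\"%s\"", k, q[[k]]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(as.character(genomeSeq(genome)))
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
}

.gffType <- function(kind) switch(kind, CDS = "CDS", hr = "repeat_region",
                                  "repeat" = "repeat_region",
                                  other = "misc_feature")

.writeGff3 <- function(genome, features, path) {
  L <- genomeLength(genome)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", genomeId(genome), L)),
             con)
  if (nrow(features)) for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    attrs <- sprintf("ID=%s;kind=%s", f$locus_tag, f$kind)
    row <- function(s, e, part) {
      a <- if (is.na(part)) attrs else sprintf("%s;part=%d", attrs, part)
      sprintf("%s\tbaculoscribe\t%s\t%d\t%d\t.\t%s\t.\t%s",
              genomeId(genome), .gffType(f$kind), s, e, f$strand, a)
    }
    if (f$end >= f$start) writeLines(row(f$start, f$end, NA), con)
    else writeLines(c(row(f$start, L, 1L), row(1L, f$end, 2L)), con)
  }
}

.writeTsv <- function(features, path) {
  utils::write.table(features[, .FEATURE_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Read a feature table from GFF3 or TSV
#'
#' Inverse of [writeAnnotation()] for the `gff3` and `tsv` formats.
#' GFF3 `part`-split origin-spanning features are re-joined by `ID`.
#'
#' @param path input file.
#' @param format `"gff3"` or `"tsv"` (default sniffed from extension).
#' @return feature data.frame.
#' @export
readFeatures <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path)) "gff3" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(start = "integer",
                                           end = "integer"))
    return(featureTable(df$locus_tag, df$start, df$end, df$strand, df$kind))
  }
  lines <- grep("^#", readLines(path, warn = FALSE),
                value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(featureTable())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  getattr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  df <- data.frame(
    start = as.integer(vapply(fields, `[`, "", 4L)),
    end = as.integer(vapply(fields, `[`, "", 5L)),
    strand = vapply(fields, `[`, "", 7L),
    attrs = vapply(fields, `[`, "", 9L), stringsAsFactors = FALSE)
  df$id <- getattr(df$attrs, "ID")
  df$kind <- getattr(df$attrs, "kind")
  df$part <- getattr(df$attrs, "part")
  out <- do.call(rbind, lapply(split(df, factor(df$id, unique(df$id))),
    function(d) {
      if (nrow(d) == 1L)
        data.frame(locus_tag = d$id, start = d$start, end = d$end,
                   strand = d$strand, kind = d$kind,
                   stringsAsFactors = FALSE)
      else {
        p1 <- d[d$part == "1", ]; p2 <- d[d$part == "2", ]
        data.frame(locus_tag = p1$id, start = p1$start, end = p2$end,
                   strand = p1$strand, kind = p1$kind,
                   stringsAsFactors = FALSE)
      }
    }))
  rownames(out) <- NULL
  featureTable(out$locus_tag, out$start, out$end, out$strand, out$kind)
}
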