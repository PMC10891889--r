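# Orchestration: hr detection first (the masking rule requires it),
# then ORF annotation, promoter scan, and optional comparative /
# demarcation stages, with a consolidated JSON report.

#' Run the full characterization pipeline
#'
#' Stage order: tandem-repeat/hr detection, ORF prediction with
#' overlap resolution and hr masking, promoter classification, then
#' optional comparative (second genome) and demarcation (marker
#' distances) stages.  All effective parameters are recorded in the
#' report; reruns with the same inputs are deterministic.
#'
#' @param genome a [CircularGenome-class], or a path readable by
#'   [readGenome()].
#' @param outDir output directory (created if needed), or `NULL` to
#'   skip file output.
#' @param minAa,maxOverlapBp ORF annotation parameters.
#' @param window promoter window size.
#' @param promoterLoci optional locus-tag subset for the promoter
#'   census.
#' @param hrParams list of [findTandemRepeats()] /
#'   [findPalindromes()] overrides.
#' @param compareWith optional second genome (or path) for the
#'   comparative stage.
#' @param markerDistances optional named distances (or
#'   [K2PResult-class] objects) for the demarcation stage.
#' @param locusPrefix prefix for final locus tags.
#' @return invisibly, a report list (also written to
#'   `report.json` when `outDir` is given) with elements `stats`,
#'   `hrs`, `promoters`, `parameters`, and optionally `comparative`,
#'   `demarcation`.
#' @export
runPipeline <- function(genome, outDir = NULL, minAa = 50,
                        maxOverlapBp = 75, window = 180,
                        promoterLoci = NULL, hrParams = list(),
                        compareWith = NULL, markerDistances = NULL,
                        locusPrefix = "orf") {
  if (is.character(genome)) genome <- readGenome(genome)$genome
  L <- genomeLength(genome)
  params <- list(min_aa = minAa, max_overlap_bp = maxOverlapBp,
                 window = window, hr = hrParams)

  trArgs <- c(list(seq = genome), hrParams[names(hrParams) %in%
    c("minPeriod", "maxPeriod", "minCopies", "minIdentity", "k",
      "minVotes")])
  arrays <- do.call(findTandemRepeats, trArgs)
  palArgs <- hrParams[names(hrParams) %in%
                        c("minArm", "maxGap", "maxMismatch")]
  hrs <- do.call(assembleHrs, c(list(arrays = arrays, genome = genome),
                                palArgs))

  orfs <- findOrfs(genome, minAa = minAa)
  orfs <- resolveOverlaps(orfs, L, maxOverlapBp = maxOverlapBp)
  orfs <- maskHrOrfs(orfs, hrs, L)
  orfs <- assignLocusTags(orfs, prefix = locusPrefix)

  calls <- scanPromoters(genome, orfs, loci = promoterLoci,
                         window = window)
  promoSummary <- if (length(calls)) promoterSummary(calls) else NULL

  stats <- genomeStats(genome, orfs)
  report <- list(
    genome_id = genomeId(genome),
    parameters = params,
    stats = stats,
    hrs = hrReport(hrs, orfs, L),
    promoters = list(
      calls = lapply(calls, function(x)
        list(locus_tag = x$locus_tag, classification = x$classification)),
      summary = promoSummary))

  if (!is.null(compareWith)) {
    if (is.character(compareWith)) compareWith <- readGenome(compareWith)$genome
    orfsB <- assignLocusTags(resolveOverlaps(
      findOrfs(compareWith, minAa = minAa), genomeLength(compareWith),
      maxOverlapBp = maxOverlapBp), prefix = "b")
    pairs <- reciprocalBestHits(
      stats::setNames(orfs$translation, orfs$locus_tag),
      stats::setNames(orfsB$translation, orfsB$locus_tag))
    par <- parityPoints(pairs, orfs$locus_tag, orfsB$locus_tag)
    report$comparative <- list(
      n_homologs = nrow(pairs),
      collinearity = par$correlation,
      whole_genome_identity = as.numeric(
        wholeGenomeIdentity(genome, compareWith)))
  }
  if (!is.null(markerDistances))
    report$demarcation <- demarcateSpecies(markerDistances)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    feats <- featureTable(orfs$locus_tag, orfs$start, orfs$end,
                          orfs$strand, rep("CDS", nrow(orfs)))
    if (length(hrs))
      feats <- rbind(feats, featureTable(
        vapply(hrs, function(h) h@name, ""),
        vapply(hrs, function(h) h@start, 1L),
        vapply(hrs, function(h) h@end, 1L),
        rep("+", length(hrs)), rep("hr", length(hrs))))
    writeAnnotation(genome, feats, file.path(outDir, "annotation.gb"),
                    "genbank")
    writeAnnotation(genome, feats, file.path(outDir, "annotation.gff3"),
                    "gff3")
    writeAnnotation(genome, feats, file.path(outDir, "features.tsv"),
                    "tsv")
    if (length(hrs)) writeHrBed(hrs, genome, file.path(outDir, "hrs.bed"))
    utils::write.table(
      data.frame(locus_tag = names(calls),
                 class = vapply(calls, `[[`, "", "classification")),
      file.path(outDir, "promoters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    rep_out <- report
    rep_out$hrs <- if (is.data.frame(report$hrs) && nrow(report$hrs))
      report$hrs[, setdiff(names(report$hrs), "units")] else NULL
    jsonlite::write_json(rep_out, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  invisible(report)
}

#' Run the pipeline from a YAML configuration file
#'
#' Reads a YAML run configuration and calls [runPipeline()].
#' Recognized keys: `genome`, `out_dir`, `min_aa`, `max_overlap_bp`,
#' `window`, `promoter_loci`, `hr` (a mapping of hr-detection
#' overrides), `compare_with`, `marker_distances` (mapping of marker
#' name to distance), `locus_prefix`.  Unset keys fall back to the
#' package defaults, which are the conventional annotation parameters.
#'
#' @param path YAML file.
#' @return the report list, invisibly (see [runPipeline()]).
#' @export
runPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$genome)) stop("config must name a 'genome' input")
  args <- list(genome = cfg$genome)
  map <- c(out_dir = "outDir", min_aa = "minAa",
           max_overlap_bp = "maxOverlapBp", window = "window",
           promoter_loci = "promoterLoci", hr = "hrParams",
           compare_with = "compareWith",
           marker_distances = "markerDistances",
           locus_prefix = "locusPrefix")
  for (key in names(map))
    if (!is.null(cfg[[key]])) args[[map[[key]]]] <- cfg[[key]]
  do.call(runPipeline, args)
}

#' Check a pipeline report against the shipped schema
#'
#' Structural validation (required fields and types) of a
#' [runPipeline()] report against `inst/schema/report-schema.json`.
#'
#' @param report report list or path to a `report.json`.
#' @return `TRUE` invisibly; errors with the list of violations
#'   otherwise.
#' @export
validateReport <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "baculoscribe"))
  problems <- character()
  for (k in unlist(schema$required))
    if (is.null(report[[k]]))
      problems <- c(problems, paste0("missing required field: ", k))
  statreq <- unlist(schema$properties$stats$required)
  for (k in statreq)
    if (is.null(report$stats[[k]]))
      problems <- c(problems, paste0("missing stats field: ", k))
  if (!is.null(report$stats$orf_count) &&
      !is.numeric(unlist(report$stats$orf_count)))
    problems <- c(problems, "stats.orf_count must be numeric")
  if (length(problems)) stop(paste(problems, collapse = "; "))
  invisible(TRUE)
}
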