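#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   reverseComplement letterFrequency translate readDNAStringSet
#'   writeXStringSet pairwiseAlignment score pid nmatch alignedPattern
#'   alignedSubject
#' @importFrom stats cor median rbinom runif sd setNames
#' @importFrom utils read.delim write.table head tail
#' @useDynLib baculoscribe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setOldClass("data.frame")

#' CircularGenome: a (possibly circular) DNA genome
#'
#' Container for a single assembled genome sequence together with its
#' topology and the convention that defines coordinate 1.  Baculovirus
#' genomes are circular; by convention the polyhedrin start codon defines
#' the map origin, so the class carries an `originNote` recording which
#' feature was rotated to position 1.
#'
#' @slot id single identifier string.
#' @slot sequence a [Biostrings::DNAString] over the IUPAC DNA alphabet.
#' @slot topology `"circular"` or `"linear"`.
#' @slot originNote free-text note naming the feature that defines
#'   position 1 (e.g. `"polh ATG"`), or `NA`.
#'
#' @seealso [readGenome()], [rotateToOrigin()], [extractSubsequence()]
#' @export
setClass("CircularGenome",
  slots = c(
    id = "character",
    sequence = "ANY",
    topology = "character",
    originNote = "character"
  )
)

setValidity("CircularGenome", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be a single string")
  if (!is(object@sequence, "DNAString"))
    msg <- c(msg, "'sequence' must be a DNAString")
  else {
    if (length(object@sequence) < 1L)
      msg <- c(msg, "sequence must have length >= 1")
    nfrac <- as.numeric(
      Biostrings::letterFrequency(object@sequence, "N")) /
      length(object@sequence)
    if (!is.na(nfrac) && nfrac >= 0.05)
      msg <- c(msg, "fraction of N must be < 5%")
  }
  if (length(object@topology) != 1L ||
      !object@topology %in% c("circular", "linear"))
    msg <- c(msg, "'topology' must be \"circular\" or \"linear\"")
  if (length(msg)) msg else TRUE
})

#' Construct a CircularGenome
#'
#' @param sequence DNA sequence as a character string or
#'   [Biostrings::DNAString].
#' @param id genome identifier.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param originNote optional note describing which feature defines
#'   position 1.
#' @return A [CircularGenome-class] object.
#' @examples
#' g <- CircularGenome("ATGCATGC", id = "toy")
#' genomeLength(g)
#' @export
CircularGenome <- function(sequence, id = "genome", topology = "circular",
                           originNote = NA_character_) {
  if (is.character(sequence)) sequence <- DNAString(toupper(sequence))
  new("CircularGenome", id = id, sequence = sequence,
      topology = topology, originNote = as.character(originNote))
}

#' @describeIn CircularGenome-class genome length in bp.
#' @param x,object a `CircularGenome`.
#' @export
setMethod("length", "CircularGenome", function(x) length(x@sequence))

#' @rdname CircularGenome-class
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @describeIn CircularGenome-class the sequence as a `DNAString`.
#' @export
setMethod("genomeSeq", "CircularGenome", function(x) x@sequence)

#' @rdname CircularGenome-class
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @describeIn CircularGenome-class the identifier.
#' @export
setMethod("genomeId", "CircularGenome", function(x) x@id)

#' @rdname CircularGenome-class
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @describeIn CircularGenome-class genome length in bp.
#' @export
setMethod("genomeLength", "CircularGenome", function(x) length(x@sequence))

#' @rdname CircularGenome-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @describeIn CircularGenome-class `"circular"` or `"linear"`.
#' @export
setMethod("topology", "CircularGenome", function(x) x@topology)

#' @rdname CircularGenome-class
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @describeIn CircularGenome-class `TRUE` for circular topology.
#' @export
setMethod("isCircular", "CircularGenome",
          function(x) identical(x@topology, "circular"))

setMethod("show", "CircularGenome", function(object) {
  gc <- gcPercent(object)
  cat(sprintf("CircularGenome '%s': %d bp, %s, G+C %.2f%%\n",
              object@id, length(object), object@topology, gc))
  if (!is.na(object@originNote))
    cat("  origin: ", object@originNote, "\n", sep = "")
})

#' K2PResult: Kimura 2-parameter distance for one sequence pair
#'
#' Holds the transition proportion P, transversion proportion Q, the
#' number of compared sites after pairwise deletion of gap/N columns,
#' and the K2P distance d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)].
#' `defined` is `FALSE` when the log argument is non-positive
#' (saturation) or no sites could be compared.
#'
#' @slot P transition proportion (A<->G, C<->T).
#' @slot Q transversion proportion.
#' @slot nSites number of compared sites.
#' @slot distance K2P distance in substitutions/site (`NA` when not
#'   defined).
#' @slot defined logical.
#' @seealso [k2pDistance()], [demarcateSpecies()]
#' @export
setClass("K2PResult",
  slots = c(P = "numeric", Q = "numeric", nSites = "integer",
            distance = "numeric", defined = "logical"))

setValidity("K2PResult", function(object) {
  msg <- character()
  if (object@nSites > 0L) {
    if (object@P < 0 || object@Q < 0 || object@P + object@Q > 1 + 1e-12)
      msg <- c(msg, "P and Q must be proportions with P + Q <= 1")
  }
  if (object@defined && (is.na(object@distance) || object@distance < 0))
    msg <- c(msg, "defined results need a non-negative distance")
  if (length(msg)) msg else TRUE
})

setMethod("show", "K2PResult", function(object) {
  if (object@defined)
    cat(sprintf(
      "K2PResult: d = %.4f subs/site (P = %.4f, Q = %.4f, n = %d)\n",
      object@distance, object@P, object@Q, object@nSites))
  else
    cat(sprintf(
      "K2PResult: undefined (P = %.4f, Q = %.4f, n = %d; saturated or empty)\n",
      object@P, object@Q, object@nSites))
})

#' HrLocus: one homologous region
#'
#' A homologous region (hr) is an AT-rich locus made of adjacent tandem
#' repeat units (~112 bp in group II alphabaculoviruses), each carrying
#' an imperfect palindromic core near its center.  The object stores the
#' unit table, the majority-vote unit consensus, and the palindrome
#' found in the consensus.
#'
#' @slot name locus name (`hr1`, `hr2`, ...).
#' @slot start,end 1-based inclusive genome coordinates (end < start
#'   encodes an origin-spanning locus on a circular genome).
#' @slot units data.frame with columns `start`, `end`, `sequence`,
#'   `identity` (percent identity of the unit to the consensus).
#' @slot consensus consensus unit sequence (character).
#' @slot palindrome named list with `start`, `end`, `center`, `armLen`,
#'   `gap`, `mismatches`, `span` relative to the consensus.
#' @slot atPercent A+T percentage of the locus span (annotation only,
#'   never used as a filter).
#' @seealso [assembleHrs()], [hrReport()]
#' @export
setClass("HrLocus",
  slots = c(name = "character", start = "integer", end = "integer",
            units = "data.frame", consensus = "character",
            palindrome = "list", atPercent = "numeric"))

setValidity("HrLocus", function(object) {
  msg <- character()
  if (nrow(object@units) < 2L)
    msg <- c(msg, "an hr locus needs >= 2 repeat units")
  if (nrow(object@units) >= 2L) {
    gaps <- object@units$start[-1L] - object@units$end[-nrow(object@units)] - 1L
    if (any(gaps > 10L))
      msg <- c(msg, "consecutive units must be adjacent (gap <= 10 bp)")
  }
  p <- object@palindrome
  if (length(p) && !is.null(p$span) &&
      p$span != 2L * p$armLen + p$gap)
    msg <- c(msg, "palindrome span must equal 2*armLen + gap")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HrLocus", function(object) {
  cat(sprintf(
    "HrLocus %s: %d..%d, %d units of ~%d bp, A+T %.1f%%\n",
    object@name, object@start, object@end, nrow(object@units),
    nchar(object@consensus), object@atPercent))
  p <- object@palindrome
  if (length(p))
    cat(sprintf(
      "  palindromic core: span %d bp (arm %d, gap %d, %d mismatches) at consensus %d..%d\n",
      p$span, p$armLen, p$gap, p$mismatches, p$start, p$end))
})
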