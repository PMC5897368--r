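#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom BiocGenerics strand start end width
NULL

#' Annotated transgene vector reference
#'
#' A \code{ReferenceSet} bundles the nucleotide sequences a small-RNA library
#' is aligned to (typically one or a few linearized plasmid/vector sequences,
#' optionally plus target-gene fragments) with an annotation of their genetic
#' elements: promoters and other cis elements, 5' UTR fragments, reporter
#' ORFs, terminators, inverted terminal repeats.  Each element carries a
#' transcriptional orientation (the strand of the \code{GRanges}) so that
#' sense/antisense read classes can be defined per element rather than per
#' reference strand, and an optional \code{copy_group} naming identical
#' duplicated copies (e.g. two NLS-eGFP cassettes) between which read
#' placements cannot be distinguished.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet}, one entry per reference
#'   sequence (uppercase; N allowed).
#' @slot elements A \link[GenomicRanges]{GRanges} of annotated elements with
#'   names (element identifiers) and metadata columns \code{category} and
#'   \code{copy_group} (\code{NA} when a copy stands alone).
#'
#' @seealso \code{\link{loadReference}}, \code{\link{validateCopyGroups}}
#' @export
setClass("ReferenceSet",
  representation(sequences = "DNAStringSet", elements = "GRanges"))

setValidity("ReferenceSet", function(object) {
  msg <- character()
  seqs <- object@sequences
  el <- object@elements
  if (length(seqs) && (is.null(names(seqs)) || anyDuplicated(names(seqs))))
    msg <- c(msg, "sequences must have unique names")
  if (length(el)) {
    if (is.null(names(el)) || anyDuplicated(names(el)))
      msg <- c(msg, "elements must have unique names")
    bad <- !(as.character(GenomeInfoDb::seqnames(el)) %in% names(seqs))
    if (any(bad))
      msg <- c(msg, paste0("element '", names(el)[bad][1],
                           "' references unknown sequence '",
                           as.character(GenomeInfoDb::seqnames(el))[bad][1], "'"))
    if (!all(c("category", "copy_group") %in% colnames(mcols(el))))
      msg <- c(msg, "elements must carry 'category' and 'copy_group' metadata")
    if (any(as.character(strand(el)) == "*"))
      msg <- c(msg, "every element needs a transcriptional orientation (+/-)")
    if (!any(bad)) {
      lens <- BiocGenerics::width(seqs)[match(as.character(GenomeInfoDb::seqnames(el)),
                                              names(seqs))]
      oob <- end(el) > lens | start(el) < 1L
      if (any(oob))
        msg <- c(msg, paste0("interval out of bounds for element '",
                             names(el)[oob][1], "'"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Strand-separated per-nucleotide coverage
#'
#' Per-position read depth on the plus and minus strand of every reference
#' sequence, together with the library size used as the reads-per-million
#' (RPM) denominator.  RPM at position i is
#' \code{depth[i] / (librarySize / 1e6)}; depth and RPM are never mixed
#' across strands.
#'
#' @slot covPlus,covMinus \link[IRanges]{RleList} of per-position depth, one
#'   element per reference sequence.
#' @slot librarySize Number of reads in the library (the RPM denominator;
#'   by default all reads surviving trimming/filtering).
#' @slot countingMode \code{"all"} (each reported placement adds 1) or
#'   \code{"fractional"} (each placement adds 1/n_hits of its read).
#' @export
setClass("StrandedCoverage",
  representation(covPlus = "RleList", covMinus = "RleList",
                 librarySize = "numeric", countingMode = "character"))

setValidity("StrandedCoverage", function(object) {
  if (length(object@librarySize) != 1L || object@librarySize < 0)
    return("librarySize must be a single non-negative number")
  if (!identical(names(object@covPlus), names(object@covMinus)))
    return("plus and minus tracks must cover the same references")
  if (!object@countingMode %in% c("all", "fractional"))
    return("countingMode must be 'all' or 'fractional'")
  TRUE
})

#' Library-level read accounting
#'
#' Tracks how many raw reads survived trimming/length filtering.  The kept
#' count is the default denominator of all RPM values.
#'
#' @slot totalReads Reads kept after trimming and filtering.
#' @slot readsDiscarded Reads removed by the filter.
#' @slot lengthRangeKept Two integers, the inclusive kept-length window (nt).
#' @export
setClass("LibraryStats",
  representation(totalReads = "numeric", readsDiscarded = "numeric",
                 lengthRangeKept = "integer"))

setValidity("LibraryStats", function(object) {
  if (object@totalReads < 0 || object@readsDiscarded < 0)
    return("counts must be non-negative")
  if (length(object@lengthRangeKept) != 2L)
    return("lengthRangeKept must be [min, max]")
  TRUE
})

#' Exact-match seed index over a reference
#'
#' Hash from every plus-strand k-mer of the reference to its positions.
#' Minus-strand candidates are obtained by looking up the reverse complement
#' of a read seed, so a single strand-agnostic table serves both strands.
#'
#' @slot kmers Environment mapping k-mer string to an integer matrix with
#'   columns \code{ref} (index into \code{refNames}) and \code{pos}
#'   (1-based start on the plus strand).
#' @slot seedLength Seed k (nt).
#' @slot refSeqs Named character vector of reference sequences (plus strand).
#' @export
setClass("SeedIndex",
  representation(kmers = "environment", seedLength = "integer",
                 refSeqs = "character"))

#' Ping-pong 10-nt 5' overlap signature
#'
#' Counts of sense/antisense read pairs whose 5' ends overlap by d nt
#' (d = 1..20) within one element, and the standardized score of d = 10
#' against the other distances.  A strong positive \code{z10} is the
#' classical signature of ping-pong piRNA amplification.
#'
#' @slot counts Numeric vector of pair counts, names "1".."20".
#' @slot z10 Standardized d = 10 score; \code{NA} when undefined (fewer than
#'   two distances informative, or one strand absent).
#' @slot element Element the signature was computed over.
#' @slot nSense,nAntisense Number of 5' ends of each strand class considered.
#' @export
setClass("PingPongProfile",
  representation(counts = "numeric", z10 = "numeric", element = "character",
                 nSense = "numeric", nAntisense = "numeric"))

#' Parameters of a synthetic small-RNA library
#'
#' Describes a library with piRNA-like structure: reads concentrated on
#' annotated elements (positional hotspot mixture for the 5' ends),
#' antisense-dominant, length law peaked at 26-30 nt, 5' base biased to
#' U(T), optional sense partners with an exact 10-nt 5' overlap (ping-pong
#' pairs), background reads from the whole reference, and per-base
#' sequencing error.  With a fixed seed the generated FASTQ and manifest
#' are byte-identical across runs.
#'
#' Use \code{\link{syntheticSpec}} to construct; slots are validated there.
#' @export
setClass("SyntheticSpec",
  representation(seed = "integer", nReads = "integer",
                 elementWeights = "numeric", antisenseFraction = "numeric",
                 lengthProbs = "numeric", u5Probability = "numeric",
                 hotspotK = "integer", hotspotSpread = "numeric",
                 pingpongFraction = "numeric", errorRate = "numeric",
                 adapter = "character", readCycles = "integer",
                 hotspotSeed = "integer"))
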