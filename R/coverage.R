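#' Accumulate strand-separated per-nucleotide coverage
#'
#' Each alignment increments the depth of its strand at every position it
#' covers — by 1 in \code{"all"} mode (every reported placement counts, the
#' depth-from-all-alignments convention), or by \code{1/n_hits} in
#' \code{"fractional"} mode (each read distributes one unit across its
#' placements; provided for sensitivity analysis).  RPM at position i is
#' \code{depth[i] / (librarySize/1e6)}; the denominator defaults to the
#' library total after trimming/filtering so RPM stays comparable across
#' samples with different mapping rates (pass mapped-read counts to
#' \code{librarySize} for the mapped-denominator alternative).
#'
#' The plus and minus tracks are kept separate throughout; no net track is
#' ever computed.
#'
#' @param aln Alignment \code{GRanges} from \code{\link{alignReads}}.
#' @param ref A \linkS4class{ReferenceSet} (defines track lengths).
#' @param stats A \linkS4class{LibraryStats}, or a single number giving the
#'   library size directly.
#' @param countingMode \code{"all"} (default) or \code{"fractional"}.
#' @return A \linkS4class{StrandedCoverage}.
#' @examples
#' ref <- syntheticVectorReference()
#' idx <- buildSeedIndex(ref)
#' rd <- as.character(Biostrings::subseq(refSequences(ref)[[1]], 1101, 1128))
#' cov <- accumulateCoverage(alignReads(c(r1 = rd), idx), ref, 1e6)
#' rpmTrack(cov, names(refSequences(ref))[1], "+")[1101]
#' @export
accumulateCoverage <- function(aln, ref, stats,
                               countingMode = c("all", "fractional")) {
  countingMode <- match.arg(countingMode)
  ls <- if (methods::is(stats, "LibraryStats")) stats@totalReads else
    as.numeric(stats)
  if (is.na(ls) || ls <= 0) stop("empty library: library size must be > 0")
  lens <- BiocGenerics::width(ref@sequences)
  names(lens) <- names(ref@sequences)
  w <- if (countingMode == "fractional" && length(aln))
    1 / mcols(aln)$n_hits else rep(1, length(aln))
  covFor <- function(strandChar) {
    sub <- aln[as.character(strand(aln)) == strandChar]
    wsub <- w[as.character(strand(aln)) == strandChar]
    gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(sub),
                                 IRanges::ranges(sub))
    GenomeInfoDb::seqlevels(gr) <- names(lens)
    GenomeInfoDb::seqlengths(gr) <- lens
    GenomicRanges::coverage(gr, weight = wsub)
  }
  methods::new("StrandedCoverage", covPlus = covFor("+"),
               covMinus = covFor("-"), librarySize = ls,
               countingMode = countingMode)
}

#' @rdname coverage-accessors
#' @export
depthTrack <- function(cov, refId, strand = c("+", "-")) {
  strand <- match.arg(strand)
  rle <- if (strand == "+") cov@covPlus[[refId]] else cov@covMinus[[refId]]
  if (is.null(rle)) stop("no track for reference '", refId, "'")
  as.numeric(rle)
}

#' Extract depth and RPM tracks
#'
#' @param cov A \linkS4class{StrandedCoverage}.
#' @param refId Reference sequence name.
#' @param strand \code{"+"} or \code{"-"}.
#' @name coverage-accessors
#' @return Numeric vector over all positions of the reference (1-based).
NULL

#' @rdname coverage-accessors
#' @export
rpmTrack <- function(cov, refId, strand = c("+", "-")) {
  depthTrack(cov, refId, strand) / (cov@librarySize / 1e6)
}

#' @export
setMethod("show", "StrandedCoverage", function(object) {
  cat("StrandedCoverage over", length(object@covPlus), "reference(s);",
      "library size", object@librarySize,
      sprintf("(counting: %s)\n", object@countingMode))
  for (nm in names(object@covPlus))
    cat(sprintf("  %s: depth+ total %.1f, depth- total %.1f\n", nm,
                sum(as.numeric(object@covPlus[[nm]])),
                sum(as.numeric(object@covMinus[[nm]]))))
})

# element-restricted track on the strand carrying the given read class
elementTrack <- function(cov, ref, elementName,
                         strandClass = c("sense", "antisense"),
                         what = c("rpm", "depth")) {
  strandClass <- match.arg(strandClass)
  what <- match.arg(what)
  el <- ref@elements[elementName]
  orient <- as.character(strand(el))
  readStrand <- if (strandClass == "sense") orient else
    c("+" = "-", "-" = "+")[orient]
  refId <- as.character(GenomeInfoDb::seqnames(el))
  v <- if (what == "rpm") rpmTrack(cov, refId, readStrand) else
    depthTrack(cov, refId, readStrand)
  v[start(el):end(el)]
}

#' Compare positional small-RNA profiles between two samples
#'
#' Restricts both samples' RPM tracks to one element on the strand carrying
#' the requested read class (sense/antisense relative to the element's
#' transcriptional orientation) and quantifies positional similarity with
#' two scale-free statistics: the Spearman rank correlation across
#' positions, and the overlap fraction of top-decile positions (the
#' fraction of each sample's 10% highest-RPM positions shared by the
#' other; ties broken by coordinate for determinism).  Rank-based
#' statistics are used because absolute RPM scales differ between
#' libraries while the positional pattern is the biologically conserved
#' feature.
#'
#' @param a,b \linkS4class{StrandedCoverage} of the two samples, computed
#'   on the same reference.
#' @param ref The shared \linkS4class{ReferenceSet}.
#' @param elementName Annotated element to compare over.
#' @param strandClass \code{"sense"} or \code{"antisense"} (default).
#' @return One-row data.frame: \code{element}, \code{strand_class},
#'   \code{n_positions}, \code{spearman}, \code{top_decile_overlap}.
#'   \code{spearman} is \code{NA} when either profile is flat.
#' @export
compareProfiles <- function(a, b, ref, elementName,
                            strandClass = c("antisense", "sense")) {
  strandClass <- match.arg(strandClass)
  if (!elementName %in% names(ref@elements))
    stop("element '", elementName, "' absent from the reference annotation")
  va <- elementTrack(a, ref, elementName, strandClass)
  vb <- elementTrack(b, ref, elementName, strandClass)
  n <- length(va)
  rho <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_ else
    suppressWarnings(stats::cor(va, vb, method = "spearman"))
  k <- max(1L, ceiling(0.1 * n))
  topA <- order(-va, seq_len(n))[seq_len(k)]
  topB <- order(-vb, seq_len(n))[seq_len(k)]
  data.frame(element = elementName, strand_class = strandClass,
             n_positions = n, spearman = rho,
             top_decile_overlap = length(intersect(topA, topB)) / k,
             stringsAsFactors = FALSE)
}

# Rle -> bedGraph-style GRanges with a score per constant run
.rleToBedGraph <- function(rleList) {
  grl <- lapply(names(rleList), function(nm) {
    r <- rleList[[nm]]
    ir <- IRanges::IRanges(start = cumsum(c(1L, S4Vectors::runLength(r)))[
      seq_along(S4Vectors::runLength(r))], width = S4Vectors::runLength(r))
    gr <- GenomicRanges::GRanges(nm, ir, score = S4Vectors::runValue(r))
    gr[S4Vectors::runValue(r) != 0]
  })
  do.call(c, grl)
}

#' Export coverage tracks as bedGraph
#'
#' Writes one bedGraph per strand for either depth or RPM.  Zero runs are
#' omitted (standard sparse bedGraph).
#'
#' @param cov A \linkS4class{StrandedCoverage}.
#' @param prefix Output path prefix; files are
#'   \code{<prefix>.<what>.plus.bedGraph} and \code{...minus.bedGraph}.
#' @param what \code{"rpm"} (default) or \code{"depth"}.
#' @return Invisibly, the two paths written.
#' @export
exportBedGraph <- function(cov, prefix, what = c("rpm", "depth")) {
  what <- match.arg(what)
  scale <- if (what == "rpm") 1 / (cov@librarySize / 1e6) else 1
  paths <- c(plus = paste0(prefix, ".", what, ".plus.bedGraph"),
             minus = paste0(prefix, ".", what, ".minus.bedGraph"))
  for (s in c("plus", "minus")) {
    rl <- if (s == "plus") cov@covPlus else cov@covMinus
    gr <- .rleToBedGraph(rl)
    if (length(gr)) mcols(gr)$score <- mcols(gr)$score * scale
    rtracklayer::export(gr, paths[[s]], format = "bedGraph")
  }
  invisible(paths)
}

#' Rebuild a full-length track from a bedGraph file
#'
#' @param path bedGraph path written by \code{\link{exportBedGraph}}.
#' @param refLength Length of the reference sequence the track spans.
#' @param refId Reference name to extract (default: all records).
#' @return Numeric vector of length \code{refLength}.
#' @export
importBedGraphTrack <- function(path, refLength, refId = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(refId))
    gr <- gr[as.character(GenomeInfoDb::seqnames(gr)) == refId]
  v <- numeric(refLength)
  if (length(gr)) {
    for (j in seq_along(gr))
      v[start(gr)[j]:end(gr)[j]] <- mcols(gr)$score[j]
  }
  v
}
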