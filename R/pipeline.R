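#' Assemble a resolved pipeline configuration
#'
#' Collects every tunable of the trim-align-profile-classify pipeline into
#' one serializable list.  The resolved configuration is written verbatim
#' into the run's output directory so any run can be reproduced from its
#' outputs alone.
#'
#' @param reads Path to the input FASTQ (gzip allowed).
#' @param fasta,annotation Paths to the reference FASTA and element TSV.
#' @param outdir Output directory (created if absent).
#' @param adapter 3' adapter to trim; \code{NA} disables trimming.
#' @param minOverlap,maxMismatchRate Adapter-trim tunables
#'   (see \code{\link{trimAdapter}}).
#' @param minLen,maxLen,maxNFraction Length filter tunables
#'   (see \code{\link{filterReads}}).
#' @param seedLength,maxMismatches,maxHits Aligner tunables
#'   (see \code{\link{alignReads}}).
#' @param countingMode \code{"all"} or \code{"fractional"} depth counting.
#' @param denominator \code{"total"} (library reads after filtering; the
#'   default RPM denominator) or \code{"mapped"}.
#' @param regionRule \code{"five_prime"} or \code{"full"}
#'   (see \code{\link{assignRegions}}).
#' @param targetedElements Collapsed element labels that are MASK targets
#'   (classification and ping-pong are computed for these).
#' @param minReads,minUFraction,maskLengthRange MaskRNA verdict thresholds
#'   (see \code{\link{classifyMaskRNA}}).
#' @param writeSAM Also write a SAM file of placements.
#' @return A named list of class \code{maskRunConfig}.
#' @export
pipelineConfig <- function(reads, fasta, annotation, outdir,
                           adapter = NA_character_, minOverlap = 5L,
                           maxMismatchRate = 0.1, minLen = 15L,
                           maxLen = 45L, maxNFraction = 0.2,
                           seedLength = 12L, maxMismatches = 1L,
                           maxHits = 20L,
                           countingMode = c("all", "fractional"),
                           denominator = c("total", "mapped"),
                           regionRule = c("five_prime", "full"),
                           targetedElements = character(),
                           minReads = 50L, minUFraction = 0.6,
                           maskLengthRange = c(26L, 30L),
                           writeSAM = FALSE) {
  cfg <- list(reads = reads, fasta = fasta, annotation = annotation,
              outdir = outdir, adapter = adapter,
              minOverlap = as.integer(minOverlap),
              maxMismatchRate = maxMismatchRate,
              minLen = as.integer(minLen), maxLen = as.integer(maxLen),
              maxNFraction = maxNFraction,
              seedLength = as.integer(seedLength),
              maxMismatches = as.integer(maxMismatches),
              maxHits = as.integer(maxHits),
              countingMode = match.arg(countingMode),
              denominator = match.arg(denominator),
              regionRule = match.arg(regionRule),
              targetedElements = targetedElements,
              minReads = as.integer(minReads),
              minUFraction = minUFraction,
              maskLengthRange = as.integer(maskLengthRange),
              writeSAM = isTRUE(writeSAM))
  class(cfg) <- "maskRunConfig"
  cfg
}

.log <- function(...) message("[maskRNAprofiler] ", ...)

#' Run the full small-RNA characterization pipeline
#'
#' Executes trim (optional) - length filter - align - strand-separated
#' coverage - region/strand statistics - MaskRNA classification -
#' ping-pong signature on one library, writing all reports into
#' \code{config$outdir}: \code{config.json} (resolved configuration),
#' \code{library_stats.json}, \code{alignments.tsv} (and optional
#' \code{alignments.sam}), depth and RPM bedGraphs per strand,
#' \code{region_stats.tsv}, \code{maskrna.json}, \code{pingpong.tsv} and
#' \code{summary.json}.  The run is deterministic: identical configuration
#' and inputs give byte-identical outputs.
#'
#' @param config A configuration from \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with the in-memory results (\code{ref},
#'   \code{stats}, \code{alignments}, \code{coverage}, \code{regionStats},
#'   \code{maskrna}, \code{pingpong}, \code{summary}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "maskRunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config),
                       file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  .log("loading reference")
  ref <- loadReference(config$fasta, config$annotation)
  cgReport <- validateCopyGroups(ref)

  .log("reading FASTQ")
  raw <- readFastq(config$reads)
  if (!length(raw)) stop("empty library: no reads in ", config$reads)

  if (!is.na(config$adapter)) {
    .log("trimming 3' adapter")
    raw <- trimAdapter(raw, config$adapter, config$minOverlap,
                       config$maxMismatchRate)
  }
  .log("length filtering")
  flt <- filterReads(raw, config$minLen, config$maxLen, config$maxNFraction)
  stats <- flt$stats
  if (stats@totalReads == 0) stop("empty library: no reads pass the filter")
  jsonlite::write_json(libraryStatsToList(stats),
                       file.path(config$outdir, "library_stats.json"),
                       auto_unbox = TRUE, digits = NA)

  .log("aligning ", stats@totalReads, " reads")
  idx <- buildSeedIndex(ref, config$seedLength)
  aln <- alignReads(flt$reads, idx, config$maxMismatches, config$maxHits,
                    config$maxNFraction)
  aln <- assignRegions(aln, ref, config$regionRule)
  writeAlignmentsTSV(aln, file.path(config$outdir, "alignments.tsv"))
  if (config$writeSAM)
    writeAlignmentsSAM(aln, flt$reads,
                       file.path(config$outdir, "alignments.sam"))

  .log("computing coverage")
  nMapped <- length(unique(mcols(aln)$read_id))
  denom <- if (config$denominator == "mapped") nMapped else stats@totalReads
  cov <- accumulateCoverage(aln, ref, denom, config$countingMode)
  exportBedGraph(cov, file.path(config$outdir, "coverage"), "depth")
  exportBedGraph(cov, file.path(config$outdir, "coverage"), "rpm")

  .log("region statistics")
  rs <- regionStrandStats(aln, ref)
  utils::write.table(rs, file.path(config$outdir, "region_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  maskrna <- NULL
  ppList <- list()
  if (length(config$targetedElements)) {
    .log("MaskRNA classification")
    maskrna <- classifyMaskRNA(aln, ref, config$targetedElements,
                               config$minReads, config$minUFraction,
                               config$maskLengthRange)
    jsonlite::write_json(maskrna$verdicts,
                         file.path(config$outdir, "maskrna.json"),
                         auto_unbox = TRUE, digits = NA)
    ppRows <- lapply(config$targetedElements, function(lab) {
      elName <- if (lab %in% names(ref@elements)) lab else {
        cm <- collapseMap(ref)
        names(cm)[cm == lab][1]        # first copy represents the group
      }
      pp <- pingPongSignature(aln, ref, elName)
      data.frame(element = lab, d = seq_along(pp@counts),
                 count = unname(pp@counts), z10 = pp@z10,
                 stringsAsFactors = FALSE)
    })
    ppList <- stats::setNames(ppRows, config$targetedElements)
    utils::write.table(do.call(rbind, ppRows),
                       file.path(config$outdir, "pingpong.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    reads_total = stats@totalReads + stats@readsDiscarded,
    reads_kept = stats@totalReads,
    reads_mapped = nMapped,
    placements = length(aln),
    rpm_denominator = denom,
    reference_length = totalLength(ref),
    reference_lengths = as.list(stats::setNames(
      BiocGenerics::width(ref@sequences), names(ref@sequences))),
    copy_groups = cgReport,
    maskrna_positive = if (!is.null(maskrna))
      maskrna$verdicts$element[maskrna$verdicts$positive] else character())
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  .log("done: ", config$outdir)
  invisible(list(ref = ref, stats = stats, alignments = aln, coverage = cov,
                 regionStats = rs, maskrna = maskrna, pingpong = ppList,
                 summary = summary))
}

#' Compare positional profiles between two pipeline runs
#'
#' Re-imports the RPM bedGraph tracks written by \code{\link{runPipeline}}
#' for two run directories and delegates to \code{\link{compareProfiles}}
#' on one element and strand class.
#'
#' @param runA,runB Output directories of two pipeline runs on the same
#'   reference.
#' @param elementName Element to compare.
#' @param strandClass \code{"antisense"} (default) or \code{"sense"}.
#' @param out Optional TSV path for the comparison row.
#' @return The one-row comparison data.frame of
#'   \code{\link{compareProfiles}}.
#' @export
compareSamples <- function(runA, runB, elementName,
                           strandClass = c("antisense", "sense"),
                           out = NULL) {
  strandClass <- match.arg(strandClass)
  cfgA <- jsonlite::read_json(file.path(runA, "config.json"),
                              simplifyVector = TRUE)
  ref <- loadReference(cfgA$fasta, cfgA$annotation)
  if (!elementName %in% names(ref@elements))
    stop("element '", elementName, "' absent from the reference annotation")
  lens <- BiocGenerics::width(ref@sequences)
  names(lens) <- names(ref@sequences)
  # rebuild a StrandedCoverage holding the stored RPM values; with a 1e6
  # denominator rpmTrack() returns them unchanged
  rebuild <- function(dir) {
    tracks <- lapply(c(plus = "plus", minus = "minus"), function(side) {
      p <- file.path(dir, paste0("coverage.rpm.", side, ".bedGraph"))
      rl <- lapply(names(lens), function(refId)
        S4Vectors::Rle(importBedGraphTrack(p, lens[[refId]], refId)))
      methods::as(stats::setNames(rl, names(lens)), "RleList")
    })
    methods::new("StrandedCoverage", covPlus = tracks$plus,
                 covMinus = tracks$minus, librarySize = 1e6,
                 countingMode = "all")
  }
  res <- compareProfiles(rebuild(runA), rebuild(runB), ref, elementName,
                         strandClass)
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}
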