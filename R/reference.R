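#' Load a vector reference with element annotations
#'
#' Reads one or more reference sequences from FASTA together with a BED-like
#' element annotation and returns a validated \linkS4class{ReferenceSet}.
#' The annotation is tab-separated with columns
#' \code{chrom, start, end, name, category, strand[, copy_group]}; intervals
#' use BED convention (0-based, half-open) on disk and are held 1-based
#' inclusive in the returned \code{GRanges}.  Element intervals may overlap
#' (a UTR inside a transcription cassette is legal); overlapping elements
#' are never merged.
#'
#' Circular plasmids must be linearized at a chosen cut point before use;
#' reads spanning the cut are not modeled.
#'
#' @param fastaPath Path to the reference FASTA.
#' @param annotationPath Path to the element annotation TSV (may have a
#'   header line starting with \code{#} or \code{chrom}).
#' @return A \linkS4class{ReferenceSet}.
#' @examples
#' ref <- syntheticVectorReference()
#' td <- tempfile(); dir.create(td)
#' paths <- writeReference(ref, file.path(td, "vec.fa"), file.path(td, "vec.bed"))
#' ref2 <- loadReference(paths$fasta, paths$annotation)
#' @export
loadReference <- function(fastaPath, annotationPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  ann <- tryCatch(
    utils::read.table(annotationPath, sep = "\t", header = FALSE,
                      comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop(e)
    })
  if (is.null(ann) || !nrow(ann)) {
    gr <- GenomicRanges::GRanges(category = character(),
                                 copy_group = character())
    names(gr) <- character()
    return(methods::new("ReferenceSet", sequences = seqs, elements = gr))
  }
  if (is.character(ann[[2]])) {            # tolerate a plain header row
    ann <- ann[-1, , drop = FALSE]
    ann[[2]] <- as.integer(ann[[2]]); ann[[3]] <- as.integer(ann[[3]])
  }
  if (ncol(ann) < 6L)
    stop("annotation needs >= 6 columns: chrom start end name category strand")
  colnames(ann)[1:6] <- c("chrom", "start", "end", "name", "category", "strand")
  ann$copy_group <- if (ncol(ann) >= 7L) {
    cg <- as.character(ann[[7]])
    cg[cg %in% c("", ".", "NA")] <- NA_character_
    cg
  } else NA_character_
  bad <- !(ann$chrom %in% names(seqs))
  if (any(bad))
    stop("annotation row ", which(bad)[1], " ('", ann$name[bad][1],
         "') references missing ref_id '", ann$chrom[bad][1], "'")
  if (any(ann$start >= ann$end))
    stop("start >= end in annotation row ", which(ann$start >= ann$end)[1])
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand,
    category = ann$category, copy_group = ann$copy_group)
  names(gr) <- ann$name
  lens <- BiocGenerics::width(seqs)[match(ann$chrom, names(seqs))]
  if (any(ann$end > lens))
    stop("interval out of bounds: element '", ann$name[ann$end > lens][1], "'")
  methods::new("ReferenceSet", sequences = seqs, elements = gr)
}

#' Write a ReferenceSet back to FASTA + annotation
#'
#' Inverse of \code{\link{loadReference}}: reloading the written pair yields
#' an identical object.
#'
#' @param ref A \linkS4class{ReferenceSet}.
#' @param fastaPath,annotationPath Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
writeReference <- function(ref, fastaPath, annotationPath) {
  Biostrings::writeXStringSet(ref@sequences, fastaPath)
  el <- ref@elements
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(el)),
    start = start(el) - 1L, end = end(el), name = names(el),
    category = mcols(el)$category, strand = as.character(strand(el)),
    copy_group = ifelse(is.na(mcols(el)$copy_group), ".",
                        mcols(el)$copy_group),
    stringsAsFactors = FALSE)
  utils::write.table(df, annotationPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fastaPath, annotation = annotationPath))
}

#' @describeIn ReferenceSet-accessors Reference sequences as a DNAStringSet.
#' @export
refSequences <- function(ref) ref@sequences

#' Accessors for ReferenceSet
#'
#' @param ref A \linkS4class{ReferenceSet}.
#' @name ReferenceSet-accessors
#' @return \code{refElements}: the annotation \code{GRanges};
#'   \code{refSequences}: the \code{DNAStringSet};
#'   \code{totalLength}: total nucleotides across sequences.
NULL

#' @describeIn ReferenceSet-accessors Element annotation as GRanges.
#' @export
refElements <- function(ref) ref@elements

#' @describeIn ReferenceSet-accessors Total reference length (nt).
#' @export
totalLength <- function(ref) sum(BiocGenerics::width(ref@sequences))

# oriented element sequence: reverse-complemented for reverse elements
elementSequence <- function(ref, elementName) {
  el <- ref@elements[elementName]
  s <- Biostrings::subseq(
    ref@sequences[[as.character(GenomeInfoDb::seqnames(el))]],
    start(el), end(el))
  if (as.character(strand(el)) == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Check that duplicated vector elements are truly identical
#'
#' Elements sharing a \code{copy_group} are expected to be identical copies
#' (after reverse-complementing reverse-oriented members), so that reads
#' multi-mapping between them can be collapsed to one count per group
#' rather than double-counted.  Groups whose members' oriented sequences
#' are string-identical get status \code{"mirror"}; others are reported
#' \code{"divergent"} with a warning and left uncollapsed downstream.
#'
#' @param ref A \linkS4class{ReferenceSet}.
#' @return A data.frame with one row per copy group: \code{copy_group},
#'   \code{n_members}, \code{members} (comma-separated), \code{status}.
#' @export
validateCopyGroups <- function(ref) {
  el <- ref@elements
  cg <- mcols(el)$copy_group
  groups <- unique(cg[!is.na(cg)])
  if (!length(groups))
    return(data.frame(copy_group = character(), n_members = integer(),
                      members = character(), status = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(groups, function(g) {
    mem <- names(el)[!is.na(cg) & cg == g]
    seqs <- vapply(mem, function(m) elementSequence(ref, m), character(1))
    status <- if (length(mem) >= 2L && length(unique(seqs)) == 1L)
      "mirror" else if (length(mem) < 2L) "singleton" else "divergent"
    data.frame(copy_group = g, n_members = length(mem),
               members = paste(mem, collapse = ","), status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$status == "divergent"))
    warning("copy group(s) with non-identical members: ",
            paste(out$copy_group[out$status == "divergent"], collapse = ", "),
            " (treated as independent elements)")
  out
}

# map element name -> collapsed label (copy_group for mirror groups)
collapseMap <- function(ref) {
  el <- ref@elements
  lab <- names(el)
  rep_ <- validateCopyGroups(ref)
  mirror <- rep_$copy_group[rep_$status == "mirror"]
  cg <- mcols(el)$copy_group
  take <- !is.na(cg) & cg %in% mirror
  lab[take] <- cg[take]
  stats::setNames(lab, names(el))
}

#' @export
setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet with", length(object@sequences), "sequence(s),",
      totalLength(object), "nt total\n")
  el <- object@elements
  cat(length(el), "annotated element(s)")
  if (length(el)) {
    cg <- unique(mcols(el)$copy_group)
    cg <- cg[!is.na(cg)]
    cat(";", length(cg), "copy group(s)")
  }
  cat("\n")
  if (length(el)) {
    df <- data.frame(element = names(el),
                     ref = as.character(GenomeInfoDb::seqnames(el)),
                     start = start(el), end = end(el),
                     strand = as.character(strand(el)),
                     category = mcols(el)$category)
    print(utils::head(df, 10), row.names = FALSE)
    if (length(el) > 10) cat("...", length(el) - 10, "more\n")
  }
})
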