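#' Assign alignments to annotated elements by their 5' end
#'
#' An alignment belongs to the element containing the base at its read-strand
#' 5' end (reference position \code{start} for plus-strand placements,
#' \code{end} for minus-strand).  The 5' end is used because it is the
#' biologically sharp coordinate of piRNA-like reads; a read whose 5' end
#' lies 1 nt outside an element is unassigned no matter how much of its
#' body overlaps.  When several elements contain the 5' base (overlapping
#' annotations), the smallest element wins, ties broken by coordinate —
#' the most specific annotation.  \code{rule = "full"} instead requires the
#' whole read inside the element (sensitivity-analysis alternative).
#'
#' The strand class is \code{"sense"} when the read strand equals the
#' element's transcriptional orientation, \code{"antisense"} otherwise.
#'
#' @param aln Alignment \code{GRanges} from \code{\link{alignReads}}.
#' @param ref A \linkS4class{ReferenceSet}.
#' @param rule \code{"five_prime"} (default) or \code{"full"}.
#' @return \code{aln} with metadata columns \code{element} and
#'   \code{strand_class} added (\code{NA} for unassigned placements).
#' @export
assignRegions <- function(aln, ref, rule = c("five_prime", "full")) {
  rule <- match.arg(rule)
  el <- ref@elements
  element <- rep(NA_character_, length(aln))
  strand_class <- rep(NA_character_, length(aln))
  if (length(aln) && length(el)) {
    if (rule == "five_prime") {
      p5 <- ifelse(as.character(strand(aln)) == "+", start(aln), end(aln))
      q <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(aln),
                                  IRanges::IRanges(p5, width = 1L))
    } else {
      q <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(aln),
                                  IRanges::ranges(aln))
    }
    ov <- GenomicRanges::findOverlaps(q, el, type = "within",
                                      ignore.strand = TRUE)
    if (length(ov)) {
      h <- data.frame(q = S4Vectors::queryHits(ov),
                      s = S4Vectors::subjectHits(ov))
      h <- h[order(h$q, BiocGenerics::width(el)[h$s], h$s), ]
      h <- h[!duplicated(h$q), ]
      element[h$q] <- names(el)[h$s]
      strand_class[h$q] <- ifelse(
        as.character(strand(aln))[h$q] == as.character(strand(el))[h$s],
        "sense", "antisense")
    }
  }
  mcols(aln)$element <- element
  mcols(aln)$strand_class <- strand_class
  aln
}

# one deduplicated (read, collapsed-label, strand_class) incidence table:
# a read multi-mapped to both copies of a mirror group counts once for the
# group; multi-hits on distinct (non-mirror) elements count once per element
.readIncidences <- function(aln, ref) {
  keep <- !is.na(mcols(aln)$element)
  a <- aln[keep]
  if (!length(a))
    return(data.frame(read_id = character(), label = character(),
                      strand_class = character(), read_length = integer(),
                      first_base = character(), stringsAsFactors = FALSE))
  cm <- collapseMap(ref)
  df <- data.frame(read_id = mcols(a)$read_id,
                   label = unname(cm[mcols(a)$element]),
                   strand_class = mcols(a)$strand_class,
                   read_length = mcols(a)$read_length,
                   first_base = mcols(a)$first_base,
                   stringsAsFactors = FALSE)
  df[!duplicated(df[c("read_id", "label", "strand_class")]), ]
}

#' Length and first-nucleotide statistics per (element, strand class)
#'
#' Builds the per-region report underlying the classic small-RNA summary
#' tables: read count, length histogram over the bins 1-5, 6-10, ...,
#' 31-35, 36+ nt (percentages), mean length, and first-base percentages
#' over A/U/C/G (the DNA-sequenced T is reported as U).  Elements of a
#' mirror copy group are collapsed to a single row under the group name —
#' a read multi-mapped to both identical copies counts once.  Empty cells
#' keep count 0 with \code{NA} percentages rather than NaN.
#'
#' @param aln Assigned alignments (from \code{\link{assignRegions}}).
#' @param ref A \linkS4class{ReferenceSet}.
#' @param elements Optional character vector restricting/ordering the
#'   collapsed labels reported (default: all annotated, collapsed).
#' @return data.frame with one row per (label, strand_class): \code{element},
#'   \code{strand_class}, \code{n_reads}, \code{mean_length},
#'   \code{pct_1_5} ... \code{pct_36plus}, \code{pct_A}, \code{pct_U},
#'   \code{pct_C}, \code{pct_G}.
#' @export
regionStrandStats <- function(aln, ref, elements = NULL) {
  inc <- .readIncidences(aln, ref)
  labels <- if (is.null(elements)) unique(unname(collapseMap(ref))) else elements
  binCols <- paste0("pct_", gsub("[-+]", "_", sub("\\+$", "plus", LENGTH_BINS$label)))
  grid <- expand.grid(element = labels,
                      strand_class = c("sense", "antisense"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- inc[inc$label == grid$element[i] &
                 inc$strand_class == grid$strand_class[i], ]
    n <- nrow(sub)
    out <- data.frame(element = grid$element[i],
                      strand_class = grid$strand_class[i],
                      n_reads = n, mean_length = NA_real_,
                      stringsAsFactors = FALSE)
    out[binCols] <- NA_real_
    out[c("pct_A", "pct_U", "pct_C", "pct_G")] <- NA_real_
    if (n > 0) {
      out$mean_length <- mean(sub$read_length)
      h <- table(binLengths(sub$read_length))
      out[binCols] <- as.numeric(h) / n * 100
      fb <- toupper(sub$first_base)
      out$pct_A <- sum(fb == "A") / n * 100
      out$pct_U <- sum(fb == "T") / n * 100    # T sequenced, U reported
      out$pct_C <- sum(fb == "C") / n * 100
      out$pct_G <- sum(fb == "G") / n * 100
    }
    out
  })
  res <- do.call(rbind, rows)
  res[order(match(res$element, labels), res$strand_class != "sense"), ,
      drop = FALSE]
}

#' Classify MaskRNAs
#'
#' Applies the MaskRNA definition: reads are flagged when they are
#' (1) antisense to a targeted element and (2) 26-30 nt long; criterion
#' (3), the preferential 5' uridine, is a population property and gates
#' the element-level verdict: an element is MaskRNA-positive when its
#' flagged read count reaches \code{minReads} and the 5' U fraction among
#' flagged reads reaches \code{minUFraction}.  Mirror copy groups are
#' collapsed as in \code{\link{regionStrandStats}}.
#'
#' @param aln Assigned alignments (from \code{\link{assignRegions}}).
#' @param ref A \linkS4class{ReferenceSet}.
#' @param targetedElements Collapsed element labels that are MASK targets.
#' @param minReads Minimum flagged reads for a positive verdict (default 50).
#' @param minUFraction Minimum 5' U fraction among flagged reads
#'   (default 0.6).
#' @param lengthRange Inclusive length window of criterion (2)
#'   (default \code{c(26, 30)}).
#' @return List with \code{reads} (per-incidence data.frame with a
#'   \code{flagged} column) and \code{verdicts} (per targeted element:
#'   \code{n_flagged}, \code{u_fraction}, \code{positive}).
#' @export
classifyMaskRNA <- function(aln, ref, targetedElements, minReads = 50L,
                            minUFraction = 0.6, lengthRange = c(26L, 30L)) {
  labels <- unique(unname(collapseMap(ref)))
  bad <- setdiff(targetedElements, labels)
  if (length(bad))
    stop("targeted element(s) not annotated: ", paste(bad, collapse = ", "))
  inc <- .readIncidences(aln, ref)
  inc$flagged <- inc$strand_class == "antisense" &
    inc$label %in% targetedElements &
    inc$read_length >= lengthRange[1] & inc$read_length <= lengthRange[2]
  verdicts <- do.call(rbind, lapply(targetedElements, function(eln) {
    f <- inc[inc$flagged & inc$label == eln, ]
    uf <- if (nrow(f)) mean(toupper(f$first_base) == "T") else NA_real_
    data.frame(element = eln, n_flagged = nrow(f), u_fraction = uf,
               positive = nrow(f) >= minReads &&
                 !is.na(uf) && uf >= minUFraction,
               stringsAsFactors = FALSE)
  }))
  list(reads = inc, verdicts = verdicts)
}

#' Ping-pong 10-nt 5' overlap signature
#'
#' For every pair of opposite-strand alignments whose 5' ends fall inside
#' one element, the 5'-5' overlap distance is
#' \code{d = pos5(minus) - pos5(plus) + 1}; ping-pong amplification
#' produces an excess of pairs at exactly d = 10.  Pair counts are tallied
#' for d = 1..20 via the per-position 5'-end histograms, and
#' \code{z10 = (count[10] - mean(count[d != 10])) / sd(count[d != 10])}.
#' \code{z10} is \code{NA} when one strand has no 5' ends in the element
#' or fewer than two other distances are informative.
#'
#' @param aln Alignment \code{GRanges} (assignment not required; the
#'   element window restricts by 5'-end position).
#' @param ref A \linkS4class{ReferenceSet}.
#' @param elementName Element to compute the signature over.
#' @param maxD Largest overlap distance tallied (default 20).
#' @return A \linkS4class{PingPongProfile}.
#' @export
pingPongSignature <- function(aln, ref, elementName, maxD = 20L) {
  el <- ref@elements[elementName]
  refId <- as.character(GenomeInfoDb::seqnames(el))
  onRef <- as.character(GenomeInfoDb::seqnames(aln)) == refId
  str <- as.character(strand(aln))
  p5 <- ifelse(str == "+", start(aln), end(aln))
  inEl <- onRef & p5 >= start(el) & p5 <= end(el)
  plus5 <- p5[inEl & str == "+"]
  minus5 <- p5[inEl & str == "-"]
  counts <- stats::setNames(numeric(maxD), as.character(seq_len(maxD)))
  if (length(plus5) && length(minus5)) {
    hp <- table(plus5)
    hm <- table(minus5)
    pp <- as.integer(names(hp))
    for (d in seq_len(maxD)) {
      match5 <- as.character(pp + d - 1L)
      hit <- match5 %in% names(hm)
      counts[d] <- sum(as.numeric(hp[hit]) * as.numeric(hm[match5[hit]]))
    }
  }
  others <- counts[-10L]
  z10 <- if (length(plus5) == 0 || length(minus5) == 0 ||
             sum(others > 0) < 2 || stats::sd(others) == 0) NA_real_ else
    (counts[[10]] - mean(others)) / stats::sd(others)
  methods::new("PingPongProfile", counts = counts, z10 = z10,
               element = elementName, nSense = length(plus5),
               nAntisense = length(minus5))
}

#' @export
setMethod("show", "PingPongProfile", function(object) {
  cat("PingPongProfile for element", object@element, "\n")
  cat("  5' ends: ", object@nSense, " plus-strand, ", object@nAntisense,
      " minus-strand\n", sep = "")
  cat("  pairs at d=10:", object@counts[[10]],
      "| z10 =", if (is.na(object@z10)) "undefined" else
        sprintf("%.2f", object@z10), "\n")
})

#' @rdname PingPongProfile-accessors
#' @export
pingPongCounts <- function(x) x@counts

#' Accessors for PingPongProfile
#' @param x A \linkS4class{PingPongProfile}.
#' @name PingPongProfile-accessors
#' @return \code{pingPongCounts}: pair counts per distance;
#'   \code{pingPongZ10}: the standardized d = 10 score.
NULL

#' @rdname PingPongProfile-accessors
#' @export
pingPongZ10 <- function(x) x@z10
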