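#' Build an exact-match seed index over a reference
#'
#' Hashes every plus-strand k-mer of every reference sequence to its
#' positions.  Minus-strand placements are found by looking up the reverse
#' complement of a read seed, so one table serves both strands.
#'
#' @param ref A \linkS4class{ReferenceSet}.
#' @param seedLength Seed k in nt (default 12).  Values below 8 are allowed
#'   but trigger a warning: on a 4-letter alphabet short seeds hash many
#'   spurious positions.
#' @return A \linkS4class{SeedIndex}.
#' @export
buildSeedIndex <- function(ref, seedLength = 12L) {
  seedLength <- as.integer(seedLength)
  stopifnot(seedLength >= 1L)
  if (seedLength < 8L)
    warning("seedLength < 8: expect large candidate lists on a 4-letter alphabet")
  seqs <- as.character(ref@sequences)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_along(seqs)) {
    n <- nchar(seqs[r])
    if (n < seedLength) next
    starts <- seq_len(n - seedLength + 1L)
    kmers <- substring(seqs[r], starts, starts + seedLength - 1L)
    byk <- split(starts, kmers)
    for (km in names(byk)) {
      mat <- cbind(ref = rep.int(r, length(byk[[km]])), pos = byk[[km]])
      prev <- env[[km]]
      env[[km]] <- if (is.null(prev)) mat else rbind(prev, mat)
    }
  }
  methods::new("SeedIndex", kmers = env, seedLength = seedLength,
               refSeqs = seqs)
}

#' Query a seed index
#'
#' @param index A \linkS4class{SeedIndex}.
#' @param kmer Exact k-mer to look up (plus strand).
#' @return Integer matrix with columns \code{ref}, \code{pos}; zero rows
#'   when absent.
#' @export
seedHits <- function(index, kmer) {
  hit <- index@kmers[[kmer]]
  if (is.null(hit)) cbind(ref = integer(), pos = integer()) else hit
}

# candidate plus-strand starts of `pattern` within each reference, by
# direct scan (used when pigeonhole seeds are shorter than the index k);
# a lookahead makes the matches overlapping-complete
.scanOccurrences <- function(refSeqs, pattern) {
  out <- lapply(seq_along(refSeqs), function(r) {
    g <- gregexpr(paste0("(?=", pattern, ")"), refSeqs[r], perl = TRUE)[[1]]
    if (g[1] == -1L) return(cbind(ref = integer(), pos = integer()))
    cbind(ref = rep.int(r, length(g)), pos = as.integer(g))
  })
  do.call(rbind, out)
}

# count mismatches between precomputed integer codes and a ref window
.mismatchCount <- function(refInt, start, readInt) {
  sum(refInt[start:(start + length(readInt) - 1L)] != readInt)
}

#' Align small-RNA reads to a reference, reporting multiple placements
#'
#' An ungapped seed-and-verify aligner for 15-40 nt reads against
#' vector-scale references.  Each read is partitioned into
#' \code{maxMismatches + 1} disjoint seeds (5'-anchored; the 5' seed uses
#' the index k when the read is long enough, shorter pigeonhole seeds
#' otherwise) so that every placement with at most \code{maxMismatches}
#' end-to-end mismatches has at least one exact seed and is therefore
#' found.  Placements are verified end-to-end on both strands, sorted by
#' (mismatches, ref, start, strand; plus before minus) and truncated to
#' \code{maxHits} — deterministic, so runs are bit-reproducible.
#'
#' Reads whose N fraction exceeds \code{maxNFraction} are left unmapped and
#' recorded in \code{metadata()$unmapped}.  N never matches any base.
#'
#' @param reads Named character vector or \link[Biostrings]{DNAStringSet}.
#' @param index A \linkS4class{SeedIndex} from \code{\link{buildSeedIndex}}.
#' @param maxMismatches Maximum end-to-end mismatches (default 1).
#' @param maxHits Placement cap per read (default 20, the multi-hit
#'   convention of the profiling this aligner feeds).
#' @param maxNFraction Reads with more N than this are unmapped (default 0.2).
#' @return A \link[GenomicRanges]{GRanges} with one range per placement and
#'   metadata columns \code{read_id}, \code{mismatches}, \code{read_length},
#'   \code{n_hits} (placements reported for that read), \code{first_base}
#'   (5' base as sequenced).  \code{metadata(gr)$unmapped} holds the ids of
#'   unplaced reads; \code{metadata(gr)$n_reads} the input read count.
#'   For minus-strand placements the read's 5' end sits at \code{end(gr)}.
#' @examples
#' ref <- syntheticVectorReference()
#' idx <- buildSeedIndex(ref)
#' rd <- as.character(Biostrings::subseq(refSequences(ref)[[1]], 1101, 1128))
#' alignReads(c(r1 = rd), idx)
#' @export
alignReads <- function(reads, index, maxMismatches = 1L, maxHits = 20L,
                       maxNFraction = 0.2) {
  ids <- names(reads)                 # as.character() drops plain-vector names
  x <- unname(toupper(as.character(reads)))
  if (is.null(ids)) ids <- paste0("read_", seq_along(x))
  refSeqs <- index@refSeqs
  # recode N so that N matches nothing (not even another N) in verification
  refInt <- lapply(refSeqs, function(s) utf8ToInt(chartr("N", "!", s)))
  refLens <- nchar(refSeqs)
  k <- index@seedLength
  nseed <- maxMismatches + 1L

  acc <- vector("list", length(x))
  unmapped <- character()
  for (i in seq_along(x)) {
    s <- x[i]
    L <- nchar(s)
    if (L < 1L || nFraction(s) > maxNFraction) {
      unmapped <- c(unmapped, ids[i]); next
    }
    rc <- revcompChar(s)
    seg <- L %/% nseed
    if (seg < 1L) { unmapped <- c(unmapped, ids[i]); next }
    useIndex <- seg >= k
    slen <- if (useIndex) k else seg
    offs <- (seq_len(nseed) - 1L) * seg          # 0-based seed offsets
    candRef <- integer(); candPos <- integer(); candStr <- character()
    for (off in offs) {
      sd <- substr(s, off + 1L, off + slen)
      if (grepl("N", sd, fixed = TRUE)) next     # N never matches: seed dead
      fwd <- if (useIndex) seedHits(index, sd) else .scanOccurrences(refSeqs, sd)
      if (nrow(fwd)) {
        st <- fwd[, "pos"] - off
        candRef <- c(candRef, fwd[, "ref"]); candPos <- c(candPos, st)
        candStr <- c(candStr, rep.int("+", nrow(fwd)))
      }
      rcsd <- revcompChar(sd)
      rev <- if (useIndex) seedHits(index, rcsd) else .scanOccurrences(refSeqs, rcsd)
      if (nrow(rev)) {
        # placement [st, st+L-1] with revcomp(read)=ref window; seed at read
        # offset `off` maps to plus-strand position st + (L - off - slen)
        st <- rev[, "pos"] - (L - off - slen)
        candRef <- c(candRef, rev[, "ref"]); candPos <- c(candPos, st)
        candStr <- c(candStr, rep.int("-", nrow(rev)))
      }
    }
    if (!length(candRef)) { unmapped <- c(unmapped, ids[i]); next }
    keyed <- !duplicated(paste0(candRef, ":", candPos, candStr))
    candRef <- candRef[keyed]; candPos <- candPos[keyed]; candStr <- candStr[keyed]
    inb <- candPos >= 1L & candPos + L - 1L <= refLens[candRef]
    candRef <- candRef[inb]; candPos <- candPos[inb]; candStr <- candStr[inb]
    if (!length(candRef)) { unmapped <- c(unmapped, ids[i]); next }
    sInt <- utf8ToInt(chartr("N", "?", s)); rcInt <- utf8ToInt(chartr("N", "?", rc))
    mm <- vapply(seq_along(candRef), function(j) {
      .mismatchCount(refInt[[candRef[j]]], candPos[j],
                     if (candStr[j] == "+") sInt else rcInt)
    }, numeric(1))
    ok <- mm <= maxMismatches
    if (!any(ok)) { unmapped <- c(unmapped, ids[i]); next }
    candRef <- candRef[ok]; candPos <- candPos[ok]
    candStr <- candStr[ok]; mm <- mm[ok]
    o <- order(mm, candRef, candPos, candStr == "-")
    if (length(o) > maxHits) o <- o[seq_len(maxHits)]
    acc[[i]] <- data.frame(read_id = ids[i], ref = candRef[o],
                           start = candPos[o], strand = candStr[o],
                           mismatches = mm[o], read_length = L,
                           first_base = firstBase(s),
                           stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
  si <- GenomeInfoDb::Seqinfo(seqnames = names(refSeqs), seqlengths = refLens)
  if (is.null(hits)) {
    gr <- GenomicRanges::GRanges(seqinfo = si)
    mcols(gr) <- DataFrame(read_id = character(), mismatches = integer(),
                           read_length = integer(), n_hits = integer(),
                           first_base = character())
  } else {
    nh <- stats::ave(seq_len(nrow(hits)), hits$read_id, FUN = length)
    gr <- GenomicRanges::GRanges(
      seqnames = names(refSeqs)[hits$ref],
      ranges = IRanges::IRanges(start = hits$start,
                                width = hits$read_length),
      strand = hits$strand, seqinfo = si)
    mcols(gr) <- DataFrame(read_id = hits$read_id,
                           mismatches = as.integer(hits$mismatches),
                           read_length = as.integer(hits$read_length),
                           n_hits = as.integer(nh),
                           first_base = hits$first_base)
  }
  metadata(gr)$unmapped <- unmapped
  metadata(gr)$n_reads <- length(x)
  gr
}

#' Align one read
#'
#' Convenience wrapper around \code{\link{alignReads}} for a single read.
#'
#' @inheritParams alignReads
#' @param read A single read (character or \link[Biostrings]{DNAString}).
#' @param readId Read identifier used in the output.
#' @return A \link[GenomicRanges]{GRanges} of placements (possibly empty).
#' @export
alignRead <- function(read, index, maxMismatches = 1L, maxHits = 20L,
                      readId = "read_1") {
  alignReads(stats::setNames(as.character(read), readId), index,
             maxMismatches = maxMismatches, maxHits = maxHits)
}

#' Write alignments as TSV
#'
#' One row per placement; positions are BED-convention 0-based half-open.
#'
#' @param aln Alignment \code{GRanges} from \code{\link{alignReads}}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeAlignmentsTSV <- function(aln, path) {
  df <- data.frame(
    read_id = mcols(aln)$read_id,
    ref_id = as.character(GenomeInfoDb::seqnames(aln)),
    start = start(aln) - 1L, end = end(aln),
    strand = as.character(strand(aln)),
    mismatches = mcols(aln)$mismatches,
    read_length = mcols(aln)$read_length,
    n_hits = mcols(aln)$n_hits,
    first_base = mcols(aln)$first_base,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Minimal single-end SAM: FLAG 16 for minus-strand placements, FLAG 256
#' for secondary placements of a multi-hit read, NM tag with the mismatch
#' count.  Sequences are emitted on the reference plus strand as SAM
#' requires; qualities are omitted (*).
#'
#' @param aln Alignment \code{GRanges} from \code{\link{alignReads}}.
#' @param reads The reads that were aligned (named character or
#'   \code{DNAStringSet}), used to emit SEQ.
#' @param path Output SAM path.
#' @return Invisibly, \code{path}.
#' @export
writeAlignmentsSAM <- function(aln, reads, path) {
  seqs <- toupper(as.character(reads))
  sl <- GenomeInfoDb::seqlengths(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(sl))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, sl[[nm]]), con)
  if (length(aln)) {
    ids <- mcols(aln)$read_id
    primary <- !duplicated(ids)
    flag <- ifelse(as.character(strand(aln)) == "-", 16L, 0L) +
      ifelse(primary, 0L, 256L)
    seq_out <- seqs[ids]
    minus <- as.character(strand(aln)) == "-"
    seq_out[minus] <- revcompChar(seq_out[minus])
    lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                     ids, flag, as.character(GenomeInfoDb::seqnames(aln)),
                     start(aln), mcols(aln)$read_length, seq_out,
                     mcols(aln)$mismatches)
    writeLines(lines, con)
  }
  invisible(path)
}
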