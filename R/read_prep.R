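#' Remove a 3' adapter from small-RNA reads
#'
#' Scans each read left to right for the first position at which a prefix of
#' the adapter matches the remaining read suffix with at least
#' \code{minOverlap} aligned bases and a mismatch fraction at most
#' \code{maxMismatchRate}; the read is cut at that position.  Reads without
#' an admissible match are returned unchanged.  Taking the leftmost
#' admissible position removes partial adapters at the 3' end while never
#' splitting an insert that merely resembles the adapter more weakly than
#' the true hit.
#'
#' @param reads Character vector or \link[Biostrings]{DNAStringSet} of reads.
#' @param adapter 3' adapter sequence (non-empty).
#' @param minOverlap Minimum aligned bases for a trim (default 5).
#' @param maxMismatchRate Maximum mismatch fraction within the aligned
#'   region (default 0.1).
#' @return Trimmed reads, same class and names as the input.
#' @examples
#' trimAdapter("ACGTACGTTGGAATTC", "TGGAATTCTCGG")
#' @export
trimAdapter <- function(reads, adapter, minOverlap = 5L,
                        maxMismatchRate = 0.1) {
  stopifnot(nzchar(adapter), minOverlap >= 1L)
  .checkProb(maxMismatchRate, "maxMismatchRate")
  asXS <- methods::is(reads, "XStringSet")
  x <- as.character(reads)
  adInt <- utf8ToInt(toupper(adapter))
  m <- length(adInt)
  out <- vapply(x, function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    sInt <- utf8ToInt(toupper(s))
    # candidate trim positions: keep s[1..i], adapter aligned from i+1
    for (i in 0:(n - minOverlap)) {
      ov <- min(m, n - i)
      mm <- sum(sInt[(i + 1L):(i + ov)] != adInt[seq_len(ov)])
      if (mm <= maxMismatchRate * ov) return(substr(s, 1L, i))
    }
    s
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(x)
  if (asXS) {
    res <- Biostrings::DNAStringSet(out)
    names(res) <- names(reads)
    res
  } else {
    names(out) <- names(reads)
    out
  }
}

#' Filter reads by length and N content
#'
#' Keeps reads whose length lies in \code{[minLen, maxLen]} and whose N
#' fraction does not exceed \code{maxNFraction}.  The kept count becomes
#' \code{totalReads} of the returned \linkS4class{LibraryStats} and is the
#' default reads-per-million denominator for all downstream coverage.
#'
#' @param reads Character vector or \link[Biostrings]{DNAStringSet}.
#' @param minLen,maxLen Inclusive kept-length window in nt (default 15-45).
#' @param maxNFraction Maximum tolerated fraction of N bases (default 0.2).
#' @return List with \code{reads} (kept, same class as input) and
#'   \code{stats} (a \linkS4class{LibraryStats}).
#' @export
filterReads <- function(reads, minLen = 15L, maxLen = 45L,
                        maxNFraction = 0.2) {
  if (minLen > maxLen) stop("minLen > maxLen")
  if (minLen < 1L) stop("minLen must be >= 1")
  x <- as.character(reads)
  len <- nchar(x)
  keep <- len >= minLen & len <= maxLen & nFraction(x) <= maxNFraction
  stats <- methods::new("LibraryStats",
                        totalReads = sum(keep), readsDiscarded = sum(!keep),
                        lengthRangeKept = as.integer(c(minLen, maxLen)))
  list(reads = reads[keep], stats = stats)
}

#' @rdname LibraryStats-accessors
#' @export
librarySize <- function(x) {
  if (methods::is(x, "StrandedCoverage")) return(x@librarySize)
  x@totalReads
}

#' Accessors for LibraryStats
#'
#' @param x A \linkS4class{LibraryStats} (for \code{librarySize}, a
#'   \linkS4class{StrandedCoverage} is also accepted).
#' @name LibraryStats-accessors
#' @return \code{librarySize}: kept reads (the RPM denominator);
#'   \code{readsDiscarded}: filtered-out reads.
NULL

#' @rdname LibraryStats-accessors
#' @export
readsDiscarded <- function(x) x@readsDiscarded

#' Read a single-end FASTQ file into a named DNAStringSet
#'
#' @param path FASTQ path (gzip allowed).
#' @return A \link[Biostrings]{DNAStringSet} named by read id.
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write reads as FASTQ with constant quality
#'
#' @param reads Named \link[Biostrings]{DNAStringSet} or character vector.
#' @param path Output path; \code{.gz} suffix enables gzip.
#' @param qualityChar Phred+33 quality character applied to every base.
#' @return Invisibly, \code{path}.
#' @export
writeFastq <- function(reads, path, qualityChar = "I") {
  if (!methods::is(reads, "XStringSet")) {
    nm <- names(reads)
    reads <- Biostrings::DNAStringSet(as.character(reads))
    names(reads) <- nm
  }
  q <- Biostrings::BStringSet(strrep(qualityChar, BiocGenerics::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @export
setMethod("show", "LibraryStats", function(object) {
  cat("LibraryStats:", object@totalReads, "reads kept,",
      object@readsDiscarded, "discarded; kept-length window [",
      object@lengthRangeKept[1], ",", object@lengthRangeKept[2], "] nt\n")
})

libraryStatsToList <- function(stats) {
  list(total_reads_after_trim = stats@totalReads,
       reads_discarded = stats@readsDiscarded,
       length_range_kept = stats@lengthRangeKept)
}
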