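# independent brute-force oracles; these deliberately share no code with
# the package implementation beyond the N-never-matches convention

# every ungapped placement of `read` on either strand of every reference,
# by exhaustive scan of all offsets
oracleAlign <- function(read, refSeqs, maxMismatches) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(read, "")[[1]]]), collapse = "")
  encRef <- function(s) utf8ToInt(chartr("N", "!", s))
  rdP <- utf8ToInt(chartr("N", "?", read))
  rdM <- utf8ToInt(chartr("N", "?", rc))
  L <- length(rdP)
  out <- list()
  for (rn in names(refSeqs)) {
    rint <- encRef(refSeqs[[rn]])
    n <- length(rint)
    if (n < L) next
    nw <- n - L + 1L
    win <- matrix(rint[outer(seq_len(nw), 0:(L - 1L), "+")], nrow = nw)
    mmP <- rowSums(win != matrix(rdP, nrow = nw, ncol = L, byrow = TRUE))
    mmM <- rowSums(win != matrix(rdM, nrow = nw, ncol = L, byrow = TRUE))
    for (strand in c("+", "-")) {
      mm <- if (strand == "+") mmP else mmM
      hit <- which(mm <= maxMismatches)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          ref = rn, start = hit, strand = strand, mismatches = mm[hit],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(ref = character(), start = integer(),
                      strand = character(), mismatches = numeric()))
  res <- do.call(rbind, out)
  res[order(res$ref, res$start, res$strand), ]
}

# leftmost admissible adapter trim point by enumerating every position
oracleTrim <- function(read, adapter, minOverlap, rate) {
  n <- nchar(read)
  if (n == 0L) return("")
  for (i in 0:(n - minOverlap)) {
    ov <- min(nchar(adapter), n - i)
    mm <- sum(utf8ToInt(substr(read, i + 1L, i + ov)) !=
                utf8ToInt(substr(adapter, 1L, ov)))
    if (mm <= rate * ov) return(substr(read, 1L, i))
  }
  read
}

# per-position depth by interval stabbing, one position at a time
oracleDepth <- function(starts, ends, weights, refLen) {
  v <- numeric(refLen)
  for (j in seq_along(starts))
    v[starts[j]:ends[j]] <- v[starts[j]:ends[j]] + weights[j]
  v
}

# ping-pong pair counts by explicit pair enumeration
oraclePingPong <- function(plus5, minus5, maxD = 20L) {
  counts <- numeric(maxD)
  for (a in plus5) for (b in minus5) {
    d <- b - a + 1L
    if (d >= 1L && d <= maxD) counts[d] <- counts[d] + 1
  }
  counts
}

grToPlacementDf <- function(gr) {
  data.frame(read_id = S4Vectors::mcols(gr)$read_id,
             ref = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             mismatches = as.numeric(S4Vectors::mcols(gr)$mismatches),
             stringsAsFactors = FALSE)
}
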