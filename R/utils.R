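# internal string helpers shared across modules

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           a = "t", c = "g", g = "c", t = "a", n = "n")

# reverse complement of plain character vectors (Biostrings handles the
# DNAStringSet API surface; this avoids object churn in per-read loops)
revcompChar <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    paste(rev(.COMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# fraction of N characters in each string
nFraction <- function(x) {
  n <- nchar(x)
  cnt <- nchar(gsub("[^Nn]", "", x))
  ifelse(n == 0L, 0, cnt / n)
}

# first character, "" for empty strings
firstBase <- function(x) substr(x, 1L, 1L)

.checkProb <- function(p, what) {
  if (any(p < 0 | p > 1)) stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

# length-histogram bins used in all region reports (nt, inclusive)
LENGTH_BINS <- data.frame(
  label = c("1-5", "6-10", "11-15", "16-20", "21-25", "26-30", "31-35", "36+"),
  lo = c(1L, 6L, 11L, 16L, 21L, 26L, 31L, 36L),
  hi = c(5L, 10L, 15L, 20L, 25L, 30L, 35L, .Machine$integer.max),
  stringsAsFactors = FALSE)

binLengths <- function(len) {
  idx <- findInterval(len, LENGTH_BINS$lo)
  factor(LENGTH_BINS$label[idx], levels = LENGTH_BINS$label)
}
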