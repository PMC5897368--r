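# fixtures are built in code; all randomness is locally seeded

# write a FASTA + BED pair and load it, so the loader itself is exercised
makeRef <- function(seqs, elements = NULL, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "ref.fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), fa)
  bed <- file.path(dir, "ref.bed")
  if (is.null(elements)) {
    elements <- data.frame(chrom = character(), start = integer(),
                           end = integer(), name = character(),
                           category = character(), strand = character(),
                           copy_group = character())
  }
  write.table(elements, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  loadReference(fa, bed)
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# antisense RPM track over a forward-oriented element, via exported API
elementTrackForTest <- function(cov, ref, el) {
  e <- refElements(ref)[el]
  rpmTrack(cov, as.character(GenomeInfoDb::seqnames(e)),
           "-")[BiocGenerics::start(e):BiocGenerics::end(e)]
}

# alignment GRanges built by hand for stats-level tests
makeAln <- function(ref_id, start, width, strand, read_id, first_base,
                    refLens, n_hits = 1L, element = NULL,
                    strand_class = NULL) {
  gr <- GenomicRanges::GRanges(
    ref_id, IRanges::IRanges(start = start, width = width), strand = strand,
    seqinfo = GenomeInfoDb::Seqinfo(names(refLens), unname(refLens)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    read_id = read_id, mismatches = 0L, read_length = as.integer(width),
    n_hits = as.integer(n_hits), first_base = first_base)
  if (!is.null(element)) {
    S4Vectors::mcols(gr)$element <- element
    S4Vectors::mcols(gr)$strand_class <- strand_class
  }
  gr
}
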