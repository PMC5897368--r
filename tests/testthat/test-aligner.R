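test_that("the seed index enumerates k-mer positions on both strands", {
  ref <- makeRef(list(chr = "ACGTACGT"))
  idx <- suppressWarnings(buildSeedIndex(ref, seedLength = 4))
  hits <- seedHits(idx, "ACGT")
  expect_equal(sort(hits[, "pos"]), c(1L, 5L))
  # palindromic seed: its reverse complement is itself, so minus-strand
  # lookups hit the same intervals
  expect_equal(seedHits(idx, "ACGT"), hits)
  expect_equal(nrow(seedHits(idx, "GGGG")), 0L)
  # empty reference -> empty index
  empty <- makeRef(list(chr = "ACG"))
  idx0 <- buildSeedIndex(empty, seedLength = 12)
  expect_equal(length(ls(idx0@kmers)), 0L)
})

test_that("identity and reverse-complement placements are found exactly", {
  withr::with_seed(20, {
    s <- randSeq(400)
    ref <- makeRef(list(chr = s))
    idx <- buildSeedIndex(ref)
    rd <- substr(s, 11, 38)
    a <- alignRead(rd, idx)
    expect_equal(length(a), 1L)
    expect_equal(BiocGenerics::start(a), 11L)
    expect_equal(as.character(BiocGenerics::strand(a)), "+")
    expect_equal(S4Vectors::mcols(a)$mismatches, 0L)
    # reverse complement maps to the same interval on the minus strand,
    # with the 5' end at the interval end
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
    b <- alignRead(rc, idx)
    expect_equal(BiocGenerics::start(b), 11L)
    expect_equal(BiocGenerics::end(b), 38L)
    expect_equal(as.character(BiocGenerics::strand(b)), "-")
  })
})

test_that("placement sets equal brute-force enumeration for 0-2 mismatches", {
  withr::with_seed(21, {
    refSeqs <- list(vecA = randSeq(1200), vecB = randSeq(800))
    ref <- makeRef(refSeqs)
    idx <- buildSeedIndex(ref)
    reads <- c(
      # reference-derived reads with 0-3 injected substitutions
      vapply(1:60, function(i) {
        src <- sample(names(refSeqs), 1)
        L <- sample(15:40, 1)
        st <- sample(nchar(refSeqs[[src]]) - L + 1, 1)
        rd <- substr(refSeqs[[src]], st, st + L - 1)
        if (runif(1) < 0.5)
          rd <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(rd)))
        for (p in sample(L, sample(0:3, 1)))
          substr(rd, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(rd, p, p)), 1)
        rd
      }, character(1)),
      # fully random reads (mostly unmappable)
      vapply(1:20, function(i) randSeq(sample(15:40, 1)), character(1)))
    names(reads) <- paste0("r", seq_along(reads))
    for (mm in 0:2) {
      got <- alignReads(reads, idx, maxMismatches = mm, maxHits = 10000L)
      gotDf <- grToPlacementDf(got)
      byRead <- split(gotDf[-1], gotDf$read_id)
      for (rn in names(reads)) {
        want <- oracleAlign(reads[[rn]], refSeqs, mm)
        rownames(want) <- NULL
        g <- byRead[[rn]]
        if (is.null(g) || nrow(g) == 0L) {
          expect_equal(nrow(want), 0L, info = paste(rn, "mm", mm))
        } else {
          g <- g[order(g$ref, g$start, g$strand), ]
          rownames(g) <- NULL
          expect_equal(g, want, info = paste(rn, "mm", mm))
        }
      }
    }
  })
})

test_that("aligning a reverse complement swaps strands, keeps intervals", {
  withr::with_seed(22, {
    s <- randSeq(1000)
    ref <- makeRef(list(chr = s))
    idx <- buildSeedIndex(ref)
    for (i in 1:20) {
      L <- sample(16:36, 1)
      st <- sample(1000 - L + 1, 1)
      rd <- substr(s, st, st + L - 1)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rd)))
      a <- alignRead(rd, idx, maxMismatches = 1)
      b <- alignRead(rc, idx, maxMismatches = 1)
      expect_equal(sort(BiocGenerics::start(a)), sort(BiocGenerics::start(b)))
      sw <- c("+" = "-", "-" = "+")
      ta <- table(as.character(BiocGenerics::strand(a)))
      tb <- table(as.character(BiocGenerics::strand(b)))
      expect_equal(sort(as.numeric(ta)), sort(as.numeric(tb)))
      for (str in names(ta)) expect_equal(unname(ta[[str]]),
                                          unname(tb[[sw[[str]]]]))
    }
  })
})

test_that("reads inside a mirror copy group hit each copy equally", {
  ref <- syntheticVectorReference()
  idx <- buildSeedIndex(ref)
  el <- refElements(ref)
  copies <- el[c("eGFP_ORF_1", "eGFP_ORF_2")]
  s <- as.character(refSequences(ref)[[1]])
  withr::with_seed(23, {
    for (i in 1:10) {
      L <- sample(20:32, 1)
      off <- sample(BiocGenerics::width(copies)[1] - L, 1)
      st <- BiocGenerics::start(copies)[1] + off
      a <- alignRead(substr(s, st, st + L - 1), idx)
      inCopy <- function(j)
        sum(BiocGenerics::start(a) >= BiocGenerics::start(copies)[j] &
              BiocGenerics::end(a) <= BiocGenerics::end(copies)[j])
      expect_equal(inCopy(1), inCopy(2))
      expect_gte(inCopy(1), 1)
    }
  })
})

test_that("hit cap, ordering and N handling follow the contract", {
  ref <- makeRef(list(chr = strrep("ACGT", 100)))
  idx <- buildSeedIndex(ref)
  rd <- strrep("ACGT", 7)
  all_hits <- alignRead(rd, idx, maxMismatches = 0, maxHits = 10000L)
  capped <- alignRead(rd, idx, maxMismatches = 0, maxHits = 20L)
  expect_gt(length(all_hits), 20L)
  expect_equal(length(capped), 20L)
  # truncation is deterministic: the capped set is the sorted head
  expect_equal(BiocGenerics::start(capped),
               sort(BiocGenerics::start(all_hits))[1:20])
  # a read that is >20% N is unmapped, recorded, not an error
  nRead <- paste0(strrep("N", 10), strrep("ACGT", 5))
  names(nRead) <- "nr"
  out <- alignReads(nRead, idx)
  expect_equal(length(out), 0L)
  expect_equal(S4Vectors::metadata(out)$unmapped, "nr")
})
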