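# shared fixture: 100-nt reference, forward ORF at [11,70], forward 5'UTR
# at [3,9], with position 10 annotated to neither
statsRef <- function() {
  withr::with_seed(40, {
    makeRef(list(chr = randSeq(100)),
            data.frame(chrom = "chr", start = c(2, 10), end = c(9, 70),
                       name = c("UTR", "ORF"), category = c("five_prime_utr",
                                                            "orf"),
                       strand = "+", copy_group = "."))
  })
}

test_that("region assignment follows the 5'-end containment rule", {
  ref <- statsRef()
  lens <- c(chr = 100L)
  # plus-strand read starting inside the forward ORF -> (ORF, sense)
  a <- assignRegions(makeAln("chr", 20, 28, "+", "r1", "T", lens), ref)
  expect_equal(S4Vectors::mcols(a)$element, "ORF")
  expect_equal(S4Vectors::mcols(a)$strand_class, "sense")
  # minus-strand read whose 5' end (interval end) is inside the UTR
  b <- assignRegions(makeAln("chr", 1, 8, "-", "r2", "T", lens), ref)
  expect_equal(S4Vectors::mcols(b)$element, "UTR")
  expect_equal(S4Vectors::mcols(b)$strand_class, "antisense")
  # 5' end 1 nt upstream of the ORF -> unassigned despite 27/28 nt overlap
  c <- assignRegions(makeAln("chr", 10, 28, "+", "r3", "T", lens), ref)
  expect_true(is.na(S4Vectors::mcols(c)$element))
  # boundary: 5' end exactly at the ORF start -> assigned
  d <- assignRegions(makeAln("chr", 11, 28, "+", "r4", "T", lens), ref)
  expect_equal(S4Vectors::mcols(d)$element, "ORF")
})

test_that("length histogram, mean and first-base table match hand computation", {
  ref <- statsRef()
  lens <- c(chr = 100L)
  aln <- makeAln("chr", c(20, 22, 24, 26), c(28, 28, 30, 22), "-",
                 paste0("r", 1:4), c("T", "T", "T", "A"), lens)
  aln <- assignRegions(aln, ref)
  rs <- regionStrandStats(aln, ref)
  row <- rs[rs$element == "ORF" & rs$strand_class == "antisense", ]
  expect_equal(row$n_reads, 4)
  expect_equal(row$pct_26_30, 75)
  expect_equal(row$pct_21_25, 25)
  expect_equal(row$mean_length, 27.0)
  expect_equal(row$pct_U, 75)
  expect_equal(row$pct_A, 25)
  # single 40-nt read lands entirely in the 36+ bin
  long <- assignRegions(makeAln("chr", 15, 40, "+", "L1", "G", lens), ref)
  rsl <- regionStrandStats(long, ref)
  lr <- rsl[rsl$element == "ORF" & rsl$strand_class == "sense", ]
  expect_equal(lr$pct_36plus, 100)
  # empty cells report count 0 with NA percentages, never NaN
  empty <- rs[rs$element == "UTR" & rs$strand_class == "sense", ]
  expect_equal(empty$n_reads, 0)
  expect_true(is.na(empty$mean_length) && is.na(empty$pct_U))
  # populated histograms sum to 100
  expect_equal(sum(row[paste0("pct_", c("1_5", "6_10", "11_15", "16_20",
                                        "21_25", "26_30", "31_35",
                                        "36plus"))]), 100)
})

test_that("mirror copy groups collapse without changing total read count", {
  ref <- syntheticVectorReference()
  idx <- buildSeedIndex(ref)
  s <- as.character(refSequences(ref)[[1]])
  copies <- refElements(ref)[c("eGFP_ORF_1", "eGFP_ORF_2")]
  withr::with_seed(41, {
    reads <- vapply(1:50, function(i) {
      L <- sample(24:32, 1)
      st <- BiocGenerics::start(copies)[1] +
        sample(BiocGenerics::width(copies)[1] - L, 1)
      substr(s, st, st + L - 1)
    }, character(1))
    names(reads) <- paste0("r", 1:50)
    aln <- assignRegions(alignReads(reads, idx), ref)
    rs <- regionStrandStats(aln, ref)
    # each read hits both copies but is counted once for the group
    expect_equal(sum(rs$n_reads[rs$element == "eGFP"]), 50)
    expect_false(any(c("eGFP_ORF_1", "eGFP_ORF_2") %in% rs$element))
  })
})

test_that("MaskRNA flags apply the antisense + 26-30 nt definition", {
  ref <- statsRef()
  lens <- c(chr = 100L)
  aln <- c(
    makeAln("chr", 30, 28, "-", "anti28", "T", lens),   # flaggable
    makeAln("chr", 30, 28, "+", "sense28", "T", lens),  # sense -> no
    makeAln("chr", 30, 22, "-", "anti22", "T", lens),   # too short -> no
    makeAln("chr", 30, 31, "-", "anti31", "T", lens))   # too long -> no
  aln <- assignRegions(aln, ref)
  res <- classifyMaskRNA(aln, ref, "ORF", minReads = 1, minUFraction = 0.5)
  flg <- res$reads[res$reads$flagged, ]
  expect_equal(flg$read_id, "anti28")
  expect_true(res$verdicts$positive)
  expect_error(classifyMaskRNA(aln, ref, "nope"), "not annotated")
})

test_that("verdicts contrast high- and low-abundance antisense libraries", {
  ref <- syntheticVectorReference()
  idx <- buildSeedIndex(ref)
  run <- function(utrWeight, seed) {
    spec <- syntheticSpec(
      nReads = 2000L, seed = seed,
      elementWeights = c(Cipem_5UTR = utrWeight,
                         eGFP_ORF_1 = 0.9 - utrWeight, background = 0.1))
    lib <- generateLibrary(ref, spec)
    aln <- assignRegions(alignReads(lib$reads, idx), ref)
    classifyMaskRNA(aln, ref, "Cipem_5UTR", minReads = 50)$verdicts
  }
  high <- run(0.25, 42L)   # ~400 flagged antisense reads
  low <- run(0.003, 43L)   # ~5 flagged
  expect_true(high$positive)
  expect_gt(high$u_fraction, 0.6)
  expect_false(low$positive)
  expect_lt(low$n_flagged, 50)
})

test_that("ping-pong counts match pair enumeration and z10 behaves", {
  ref <- statsRef()
  lens <- c(chr = 100L)
  withr::with_seed(44, {
    # constructed pairs with exact 10-nt 5' overlap inside the ORF
    plus5 <- sample(20:40, 30, replace = TRUE)
    minus5 <- plus5 + 9L
    extraPlus <- sample(20:40, 10, replace = TRUE)
    extraMinus <- sample(30:60, 10, replace = TRUE)
    aln <- c(
      makeAln("chr", c(plus5, extraPlus), 20,
              "+", paste0("p", 1:40), "T", lens),
      makeAln("chr", c(minus5, extraMinus) - 19L, 20,
              "-", paste0("m", 1:40), "T", lens))
    pp <- pingPongSignature(aln, ref, "ORF")
    want <- oraclePingPong(c(plus5, extraPlus), c(minus5, extraMinus))
    expect_equal(unname(pingPongCounts(pp)), want)
    expect_gt(pingPongZ10(pp), 3)
    expect_equal(which.max(pingPongCounts(pp)), c("10" = 10L))

    # uniform random placements give a near-null z10
    up <- makeAln("chr", sample(11:50, 200, replace = TRUE), 20, "+",
                  paste0("u", 1:200), "T", lens)
    um <- makeAln("chr", sample(11:50, 200, replace = TRUE), 20, "-",
                  paste0("v", 1:200), "T", lens)
    z <- pingPongZ10(pingPongSignature(c(up, um), ref, "ORF"))
    expect_lt(abs(z), 3)

    # no sense reads -> undefined z10, all-zero counts, not an error
    pp0 <- pingPongSignature(um, ref, "ORF")
    expect_true(is.na(pingPongZ10(pp0)))
    expect_equal(sum(pingPongCounts(pp0)), 0)
  })
})
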