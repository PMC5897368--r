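test_that("a single read in a million-read library gives RPM exactly 1", {
  withr::with_seed(30, {
    ref <- makeRef(list(chr = randSeq(100)))
    aln <- makeAln("chr", start = 6, width = 28, strand = "+",
                   read_id = "r1", first_base = "T", refLens = c(chr = 100))
    cov <- accumulateCoverage(aln, ref, 1e6)
    rpm <- rpmTrack(cov, "chr", "+")
    expect_equal(rpm[6:33], rep(1.0, 28))
    expect_equal(sum(rpm), 28)
    expect_equal(sum(rpmTrack(cov, "chr", "-")), 0)
    # zero alignments -> all-zero tracks
    cov0 <- accumulateCoverage(aln[0], ref, 1e6)
    expect_equal(sum(depthTrack(cov0, "chr", "+")), 0)
    # empty library is a hard error
    expect_error(accumulateCoverage(aln, ref, 0), "empty library")
  })
})

test_that("depth equals an independent per-position recount", {
  withr::with_seed(31, {
    refLen <- 600L
    ref <- makeRef(list(chr = randSeq(refLen)))
    n <- 5000
    L <- sample(15:40, n, replace = TRUE)
    st <- vapply(L, function(l) sample(refLen - l + 1L, 1L), integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    nh <- sample(1:3, n, replace = TRUE)
    aln <- makeAln("chr", st, L, strand, paste0("r", seq_len(n)),
                   first_base = "T", refLens = c(chr = refLen), n_hits = nh)
    for (mode in c("all", "fractional")) {
      cov <- accumulateCoverage(aln, ref, 1e6, mode)
      w <- if (mode == "all") rep(1, n) else 1 / nh
      for (s in c("+", "-")) {
        sel <- strand == s
        want <- oracleDepth(st[sel], st[sel] + L[sel] - 1L, w[sel], refLen)
        expect_equal(depthTrack(cov, "chr", s), want)
      }
    }
    # strand partition: plus + minus = total per-position depth
    cov <- accumulateCoverage(aln, ref, 1e6)
    expect_equal(depthTrack(cov, "chr", "+") + depthTrack(cov, "chr", "-"),
                 oracleDepth(st, st + L - 1L, rep(1, n), refLen))
    # mass conservation: total depth = sum of read lengths over placements
    expect_equal(sum(depthTrack(cov, "chr", "+")) +
                   sum(depthTrack(cov, "chr", "-")), sum(L))
  })
})

test_that("RPM is invariant under library duplication", {
  withr::with_seed(32, {
    refLen <- 300L
    ref <- makeRef(list(chr = randSeq(refLen)))
    n <- 500
    st <- sample(refLen - 30L, n, replace = TRUE)
    aln <- makeAln("chr", st, 28L, sample(c("+", "-"), n, replace = TRUE),
                   paste0("r", seq_len(n)), "T", c(chr = refLen))
    cov1 <- accumulateCoverage(aln, ref, 1000)
    doubled <- c(aln, aln)
    cov2 <- accumulateCoverage(doubled, ref, 2000)
    expect_equal(rpmTrack(cov2, "chr", "+"), rpmTrack(cov1, "chr", "+"))
    expect_equal(rpmTrack(cov2, "chr", "-"), rpmTrack(cov1, "chr", "-"))
  })
})

test_that("bedGraph export round-trips the RPM track", {
  withr::with_seed(33, {
    refLen <- 200L
    ref <- makeRef(list(chr = randSeq(refLen)))
    st <- sample(refLen - 30L, 50, replace = TRUE)
    aln <- makeAln("chr", st, 25L, "+", paste0("r", 1:50), "T",
                   c(chr = refLen))
    cov <- accumulateCoverage(aln, ref, 12345)
    td <- withr::local_tempdir()
    paths <- exportBedGraph(cov, file.path(td, "cov"), "rpm")
    back <- importBedGraphTrack(paths[["plus"]], refLen, "chr")
    expect_equal(back, rpmTrack(cov, "chr", "+"))
  })
})

test_that("profile comparison: identity, reversal, shared vs disjoint sources", {
  ref <- syntheticVectorReference()
  idx <- buildSeedIndex(ref)
  covOf <- function(seed, hseed) {
    spec <- syntheticSpec(nReads = 2500L, seed = seed, hotspotSeed = hseed)
    lib <- generateLibrary(ref, spec)
    accumulateCoverage(alignReads(lib$reads, idx), ref, 2500)
  }
  a <- covOf(101L, 7L)
  idcmp <- compareProfiles(a, a, ref, "eGFP_ORF_1", "antisense")
  expect_equal(idcmp$spearman, 1.0)
  expect_equal(idcmp$top_decile_overlap, 1.0)

  # position-reversed copy of a hotspot profile correlates far below 1
  v <- elementTrackForTest(a, ref, "eGFP_ORF_1")
  expect_lt(suppressWarnings(cor(v, rev(v), method = "spearman")), 0.5)

  # same hotspot layout beats disjoint hotspot layouts
  b <- covOf(102L, 7L)
  c <- covOf(103L, 99L)
  same <- compareProfiles(a, b, ref, "eGFP_ORF_1", "antisense")
  disj <- compareProfiles(a, c, ref, "eGFP_ORF_1", "antisense")
  expect_gt(same$spearman, disj$spearman)
  expect_gt(same$top_decile_overlap, disj$top_decile_overlap)
})
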