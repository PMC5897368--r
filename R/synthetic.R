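#' Deterministic MASK-style transgene vector reference
#'
#' Builds a synthetic ~5.2 kb linearized transposon vector emulating the
#' architecture of maternal-knockdown (MASK) constructs: left/right
#' inverted terminal repeats (the right one the reverse-oriented copy of
#' the left), a cis-regulatory element driving a transcription cassette of
#' target-gene 5' UTR + reporter ORF + terminator, and a second identical
#' reporter ORF + terminator cassette.  Identical duplicated elements
#' share a copy group (\code{eGFP}, \code{Ter}, \code{ITR}) so that read
#' placements indistinguishable between copies can be collapsed.  The
#' sequence is deterministic (fixed internal seed) and synthetic — it is a
#' structural stand-in, not any published plasmid.
#'
#' @param seed Integer seed for the background sequence (default 20211).
#' @return A \linkS4class{ReferenceSet} with one 5200-nt sequence and
#'   eight annotated elements.
#' @export
syntheticVectorReference <- function(seed = 20211L) {
  withr::with_seed(as.integer(seed), {
    bases <- c("A", "C", "G", "T")
    rseq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
    itr <- rseq(250)
    prom <- rseq(500)
    utr <- rseq(300)
    orf <- rseq(720)
    ter <- rseq(250)
    layout <- list(
      ITR_L = list(seq = itr, strand = "+", category = "itr", cg = "ITR"),
      gap1 = list(seq = rseq(50)),
      cis_promoter = list(seq = prom, strand = "+",
                          category = "promoter/cis-element", cg = NA),
      Cipem_5UTR = list(seq = utr, strand = "+", category = "five_prime_utr",
                        cg = NA),
      eGFP_ORF_1 = list(seq = orf, strand = "+", category = "orf",
                        cg = "eGFP"),
      Ter_1 = list(seq = ter, strand = "+", category = "terminator",
                   cg = "Ter"),
      gap2 = list(seq = rseq(230)),
      eGFP_ORF_2 = list(seq = orf, strand = "+", category = "orf",
                        cg = "eGFP"),
      Ter_2 = list(seq = ter, strand = "+", category = "terminator",
                   cg = "Ter"),
      gap3 = list(seq = rseq(1680)),
      ITR_R = list(seq = revcompChar(itr), strand = "-", category = "itr",
                   cg = "ITR"))
    full <- paste(vapply(layout, `[[`, character(1), "seq"), collapse = "")
    pos <- 1L
    rows <- list()
    for (nm in names(layout)) {
      w <- nchar(layout[[nm]]$seq)
      if (!is.null(layout[[nm]]$strand))
        rows[[nm]] <- data.frame(name = nm, start = pos, end = pos + w - 1L,
                                 strand = layout[[nm]]$strand,
                                 category = layout[[nm]]$category,
                                 cg = layout[[nm]]$cg,
                                 stringsAsFactors = FALSE)
      pos <- pos + w
    }
    ann <- do.call(rbind, rows)
    seqs <- Biostrings::DNAStringSet(c(MASK_vector = full))
    gr <- GenomicRanges::GRanges("MASK_vector",
                                 IRanges::IRanges(ann$start, ann$end),
                                 strand = ann$strand,
                                 category = ann$category,
                                 copy_group = ann$cg)
    names(gr) <- ann$name
    methods::new("ReferenceSet", sequences = seqs, elements = gr)
  })
}

# default length law: discretized normal on [15,40], mean 28, sd 1.5 --
# the 26-30 nt piRNA-like mode
.defaultLengthProbs <- function() {
  lens <- 15:40
  p <- stats::dnorm(lens, mean = 28, sd = 1.5)
  stats::setNames(p / sum(p), as.character(lens))
}

#' Construct a synthetic library specification
#'
#' Defaults describe the piRNA-like structure of an ovary library from a
#' silencing-positive transgenic line: reads dominated by the transcribed
#' elements of the vector, 90\% antisense, length law peaked at 26-30 nt
#' with mean 28, 5' base forced to U(T) with probability 0.874, per-base
#' substitution error 0.001.
#'
#' @param nReads Number of reads (default 50000).
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @param elementWeights Named fractions of reads per annotated element;
#'   the reserved name \code{"background"} draws reads uniformly from the
#'   whole reference with random strand.  Must sum to 1.
#' @param antisenseFraction Probability an element read is antisense to
#'   its element (scalar, or named per element; default 0.9).
#' @param lengthProbs Named probability vector over read lengths (names =
#'   nt); default discretized normal, mean 28, sd 1.5, on 15-40 nt.
#' @param u5Probability Chance the 5' base is forced to T (default 0.874);
#'   unforced reads keep the reference base, so first-base bias is
#'   isolated from background composition.
#' @param hotspotK Positional hotspots per element for 5' ends (default 5).
#' @param hotspotSpread Hotspot standard deviation in nt (default 3).
#' @param pingpongFraction Fraction of reads emitted as sense partners
#'   with an exact 10-nt 5' overlap to an antisense read (default 0).
#' @param errorRate Per-base substitution probability (default 0.001).
#' @param adapter Optional 3' adapter appended to each insert (reads then
#'   truncated to \code{readCycles} nt, emulating fixed-cycle sequencing).
#' @param readCycles Sequencer read length when an adapter is appended
#'   (default 50).
#' @param hotspotSeed Separate seed for the hotspot layout (default: the
#'   main seed).  Two specs sharing \code{hotspotSeed} but differing in
#'   \code{seed} emulate independent libraries from the same biological
#'   source — same positional hotspots, different reads.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nReads = 50000L, seed = 1L,
                          elementWeights = c(Cipem_5UTR = 0.25,
                                             eGFP_ORF_1 = 0.65,
                                             background = 0.10),
                          antisenseFraction = 0.9,
                          lengthProbs = .defaultLengthProbs(),
                          u5Probability = 0.874,
                          hotspotK = 5L, hotspotSpread = 3,
                          pingpongFraction = 0, errorRate = 0.001,
                          adapter = NA_character_, readCycles = 50L,
                          hotspotSeed = NA_integer_) {
  if (abs(sum(elementWeights) - 1) > 1e-8)
    stop("elementWeights must sum to 1")
  .checkProb(c(antisenseFraction, u5Probability, pingpongFraction,
               errorRate), "probabilities")
  if (is.null(names(lengthProbs)))
    stop("lengthProbs must be named by read length (nt)")
  methods::new("SyntheticSpec",
               seed = as.integer(seed), nReads = as.integer(nReads),
               elementWeights = elementWeights,
               antisenseFraction = antisenseFraction,
               lengthProbs = lengthProbs / sum(lengthProbs),
               u5Probability = u5Probability,
               hotspotK = as.integer(hotspotK),
               hotspotSpread = hotspotSpread,
               pingpongFraction = pingpongFraction,
               errorRate = errorRate, adapter = adapter,
               readCycles = as.integer(readCycles),
               hotspotSeed = as.integer(hotspotSeed))
}

# substitute bases at given positions with a uniformly different base
.mutate <- function(seqs, which, pos, alt) {
  for (j in seq_along(which)) {
    i <- which[j]
    old <- substr(seqs[i], pos[j], pos[j])
    choices <- setdiff(c("A", "C", "G", "T"), old)
    substr(seqs[i], pos[j], pos[j]) <- choices[alt[j]]
  }
  seqs
}

#' Generate a synthetic small-RNA library with ground truth
#'
#' Draws reads according to a \linkS4class{SyntheticSpec}: element reads
#' place their 5' ends by a per-element hotspot mixture, antisense reads
#' are reverse complements of the sampled reference interval, ping-pong
#' partner reads are sense reads whose 5' end overlaps a sampled antisense
#' read's 5' end by exactly 10 nt, background reads come uniformly from
#' the whole reference on a random strand.  The 5' base is forced to T
#' with the configured probability before sequencing error is applied.
#' Output is deterministic under the spec's seed.
#'
#' @param ref A \linkS4class{ReferenceSet}.
#' @param spec A \linkS4class{SyntheticSpec}.
#' @param fastqPath Optional path; when given the reads (with adapter, if
#'   configured) are written as FASTQ.
#' @param manifestPath Optional path for the manifest TSV.
#' @return List with \code{reads} (named \code{DNAStringSet}, inserts
#'   without adapter), \code{fastqReads} (as sequenced: adapter appended
#'   and truncated to \code{readCycles}, when an adapter is configured),
#'   \code{manifest} (one row per read: \code{read_id}, \code{origin},
#'   \code{ref_id}, \code{strand}, \code{strand_class}, \code{pos5_0based},
#'   \code{length}, \code{first_base}, \code{u5_forced},
#'   \code{pp_partner}), and \code{summaries} (realized per-origin
#'   antisense fraction, 5' U percentage and mean length).
#' @export
generateLibrary <- function(ref, spec, fastqPath = NULL,
                            manifestPath = NULL) {
  elNames <- setdiff(names(spec@elementWeights), "background")
  missingEl <- setdiff(elNames, names(ref@elements))
  if (length(missingEl))
    stop("weight on unannotated element(s): ",
         paste(missingEl, collapse = ", "))
  refChar <- as.character(ref@sequences)
  refLens <- nchar(refChar)
  el <- ref@elements
  asFrac <- function(e) {
    if (!is.null(names(spec@antisenseFraction)))
      spec@antisenseFraction[[e]] else spec@antisenseFraction
  }
  # per-(element, strand-class) hotspot mixtures for 5' ends: sense and
  # antisense reads arise from different precursors, so their positional
  # hotspots are drawn independently; the layout has its own seed so two
  # libraries can share hotspots while sampling different reads
  hsSeed <- if (is.na(spec@hotspotSeed)) spec@seed else spec@hotspotSeed
  hs <- withr::with_seed(hsSeed, {
    out <- lapply(elNames, function(e) {
      lo <- start(el[e]); hi <- end(el[e])
      lapply(c(sense = "sense", antisense = "antisense"), function(sc)
        list(center = round(stats::runif(spec@hotspotK, lo, hi)),
             w = { w <- stats::rexp(spec@hotspotK); w / sum(w) }))
    })
    names(out) <- elNames
    out
  })
  withr::with_seed(spec@seed, {
    n <- spec@nReads
    npp <- round(spec@pingpongFraction * n)
    nbase <- n - npp
    origin <- sample(names(spec@elementWeights), nbase, replace = TRUE,
                     prob = spec@elementWeights)
    lens <- as.integer(sample(names(spec@lengthProbs), nbase, replace = TRUE,
                              prob = spec@lengthProbs))
    refIdx <- integer(nbase); pos5 <- integer(nbase)
    strandV <- character(nbase); strandClass <- rep(NA_character_, nbase)
    isBg <- origin == "background"
    if (any(isBg)) {
      nb <- sum(isBg)
      refIdx[isBg] <- sample.int(length(refChar), nb, replace = TRUE,
                                 prob = refLens)
      strandV[isBg] <- sample(c("+", "-"), nb, replace = TRUE)
      u <- stats::runif(nb)
      L <- lens[isBg]
      maxs <- refLens[refIdx[isBg]] - L + 1L
      st <- 1L + floor(u * maxs)               # plus-strand interval start
      pos5[isBg] <- ifelse(strandV[isBg] == "+", st, st + L - 1L)
    }
    for (e in elNames) {
      sel <- which(origin == e)
      if (!length(sel)) next
      refIdx[sel] <- match(as.character(GenomeInfoDb::seqnames(el[e])),
                           names(refChar))
      anti <- stats::rbinom(length(sel), 1L, asFrac(e)) == 1L
      strandClass[sel] <- ifelse(anti, "antisense", "sense")
      orient <- as.character(strand(el[e]))
      strandV[sel] <- ifelse(anti == (orient == "+"), "-", "+")
      p <- numeric(length(sel))
      for (sc in c("sense", "antisense")) {
        grp <- which(strandClass[sel] == sc)
        if (!length(grp)) next
        mix <- hs[[e]][[sc]]
        comp <- sample.int(spec@hotspotK, length(grp), replace = TRUE,
                           prob = mix$w)
        p[grp] <- round(stats::rnorm(length(grp), mix$center[comp],
                                     spec@hotspotSpread))
      }
      p <- pmin(pmax(p, start(el[e])), end(el[e]))
      # clamp so the read body stays on the reference
      L <- lens[sel]
      p <- ifelse(strandV[sel] == "+", pmin(p, refLens[refIdx[sel]] - L + 1L),
                  pmax(p, L))
      pos5[sel] <- p
    }
    ppPartner <- rep(NA_character_, nbase)

    # ping-pong partners: sense reads 5'-overlapping an antisense read by 10
    if (npp > 0L) {
      antiIdx <- which(strandClass == "antisense")
      if (!length(antiIdx)) {
        warning("pingpongFraction > 0 but no antisense reads to pair with")
        npp <- 0L
      }
    }
    if (npp > 0L) {
      mate <- sample(antiIdx, npp, replace = TRUE)
      ppLens <- as.integer(sample(names(spec@lengthProbs), npp,
                                  replace = TRUE, prob = spec@lengthProbs))
      mStrand <- strandV[mate]
      pStrand <- ifelse(mStrand == "-", "+", "-")
      pPos5 <- ifelse(mStrand == "-", pos5[mate] - 9L, pos5[mate] + 9L)
      pPos5 <- pmin(pmax(pPos5, 1L), refLens[refIdx[mate]])
      # keep the 5' end fixed (it defines the 10-nt overlap); shorten the
      # read if the 3' end would leave the reference
      maxLen <- ifelse(pStrand == "+", refLens[refIdx[mate]] - pPos5 + 1L,
                       pPos5)
      ppLens <- pmax(pmin(ppLens, maxLen), 1L)
      origin <- c(origin, origin[mate])
      lens <- c(lens, ppLens)
      refIdx <- c(refIdx, refIdx[mate])
      pos5 <- c(pos5, pPos5)
      strandV <- c(strandV, pStrand)
      strandClass <- c(strandClass, ifelse(strandClass[mate] == "antisense",
                                           "sense", "antisense"))
      ppPartner <- c(ppPartner, sprintf("read_%06d", mate))
    }
    n <- length(origin)
    ids <- sprintf("read_%06d", seq_len(n))

    st <- ifelse(strandV == "+", pos5, pos5 - lens + 1L)
    en <- st + lens - 1L
    seqs <- character(n)
    for (r in unique(refIdx)) {
      sel <- refIdx == r
      seqs[sel] <- substring(refChar[r], st[sel], en[sel])
    }
    minus <- strandV == "-"
    if (any(minus))
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))

    forced <- stats::runif(n) < spec@u5Probability
    substr(seqs[forced], 1L, 1L) <- "T"

    if (spec@errorRate > 0) {
      nerr <- stats::rbinom(n, lens, spec@errorRate)
      hasErr <- which(nerr > 0L)
      for (i in hasErr) {
        p <- sample.int(lens[i], nerr[i])
        seqs <- .mutate(seqs, rep.int(i, nerr[i]), p,
                        sample.int(3L, nerr[i], replace = TRUE))
      }
    }
    names(seqs) <- ids

    manifest <- data.frame(
      read_id = ids, origin = origin, ref_id = names(refChar)[refIdx],
      strand = strandV, strand_class = strandClass,
      pos5_0based = pos5 - 1L, length = lens,
      first_base = firstBase(seqs), u5_forced = forced,
      pp_partner = ppPartner, stringsAsFactors = FALSE)

    fastqReads <- seqs
    if (!is.na(spec@adapter)) {
      fastqReads <- substr(paste0(seqs, spec@adapter), 1L, spec@readCycles)
      names(fastqReads) <- ids
    }
    out <- list(reads = Biostrings::DNAStringSet(seqs),
                fastqReads = Biostrings::DNAStringSet(fastqReads),
                manifest = manifest,
                summaries = manifestSummaries(manifest))
    if (!is.null(fastqPath)) writeFastq(out$fastqReads, fastqPath)
    if (!is.null(manifestPath))
      utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    out
  })
}

#' Realized per-origin summaries of a ground-truth manifest
#'
#' Recomputes, from the per-read manifest rows, the empirical antisense
#' fraction, 5' U percentage and mean read length per origin element —
#' the quantities the analysis pipeline is expected to recover.
#'
#' @param manifest Manifest data.frame from \code{\link{generateLibrary}}.
#' @return data.frame with one row per origin: \code{origin}, \code{n},
#'   \code{antisense_fraction}, \code{u5_pct}, \code{mean_length}.
#' @export
manifestSummaries <- function(manifest) {
  sp <- split(manifest, manifest$origin)
  do.call(rbind, lapply(names(sp), function(o) {
    m <- sp[[o]]
    data.frame(origin = o, n = nrow(m),
               antisense_fraction = if (all(is.na(m$strand_class)))
                 NA_real_ else mean(m$strand_class == "antisense",
                                    na.rm = TRUE),
               u5_pct = mean(toupper(m$first_base) == "T") * 100,
               mean_length = mean(m$length),
               stringsAsFactors = FALSE)
  }))
}
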