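---
title: "Profiling piRNA-like small RNAs over transgene vectors: methods and design"
author: "maskRNAprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling piRNA-like small RNAs over transgene vectors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskRNAprofiler)
```

## The problem

Transgene-mediated silencing of maternal transcripts in *Ciona* ovaries
(maternal mRNA-specific knockdown, MASK) is accompanied by a population of
small RNAs with piRNA hallmarks: they are predominantly antisense to the
targeted genes, about 26–30 nt long, and carry a 5′-uridine bias.  Deciding
whether a sequencing library contains such "MaskRNAs" — and where along the
transgene vector they arise — requires a small, well-controlled analysis
chain: map 15–40 nt reads onto an annotated vector reference, keep the two
strands strictly separate, normalize per-nucleotide depth to library size,
stratify length and first-nucleotide statistics by annotated element and by
sense/antisense class, and summarize positional patterns so libraries can
be compared.  `maskRNAprofiler` implements that chain end to end, together
with a ground-truth synthetic library generator so every stage is testable
without any external data.

## Data model

A `ReferenceSet` couples the vector sequence(s) (`DNAStringSet`) with a
`GRanges` of annotated elements: promoters/cis elements, target-gene 5′
UTR fragments, reporter ORFs, terminators, ITRs.  Two conventions matter
throughout:

* **Orientation is per element, not per reference strand.**  MASK vectors
  carry cassettes in both orientations, so "sense" and "antisense" are
  defined relative to each element's transcriptional direction (the strand
  of its `GRanges` entry).
* **Identical duplicated elements form copy groups.**  Vectors often carry
  two identical copies of a reporter cassette; reads mapping inside them
  cannot be attributed to one copy.  `validateCopyGroups()` verifies that
  group members are string-identical after orientation normalization
  ("mirror" groups); statistics then collapse mirror groups so a read
  multi-mapped to both copies is counted once for the group.  Groups that
  fail the identity check are reported "divergent" and left uncollapsed.

Annotations are exchanged as BED-like TSV (0-based, half-open on disk;
1-based inclusive in memory, following Bioconductor practice).  Circular
plasmids must be linearized at a chosen cut point; reads spanning the cut
are not modeled, matching how vector-scale profiles are conventionally
drawn.

## Alignment

Reads of 15–40 nt against a few kilobases of reference do not need a
genome-scale mapper, but they do need *exhaustive* multi-hit reporting:
duplicated elements make multi-mapping the norm rather than the exception,
and per-base depth is accumulated from every reported placement (up to 20
per read by default).  `alignReads()` is an ungapped seed-and-verify
aligner with an explicit completeness guarantee:

* the read is partitioned into `maxMismatches + 1` disjoint seeds
  (5′-anchored, because the 5′ end is the biologically sharp coordinate of
  piRNA-like reads; the 5′ seed uses the 12-mer index whenever the read is
  long enough, shorter pigeonhole seeds otherwise);
* any placement with at most `maxMismatches` end-to-end mismatches leaves
  at least one seed exact — mismatches can spoil at most `maxMismatches`
  of the disjoint seeds — so collecting candidates from every seed on both
  strands and verifying them end-to-end finds the complete placement set.

A single fixed seed cannot give this guarantee for nonzero mismatch
budgets (a mismatch inside the seed hides a valid placement), which is why
the seeding is pigeonhole-based.  The test suite holds the aligner to the
guarantee literally: placement sets are compared against brute-force
enumeration over all offsets and both strands for mismatch budgets 0–2.

Indels are not modeled: at these read lengths, and for positional depth
profiles, gapped placements would change no reported statistic.  `N`
matches nothing (not even another `N`); reads with more than 20% `N` are
left unmapped.  Output order is deterministic — placements sort by
(mismatches, reference, start, strand) before the `maxHits` cut — so runs
are bit-reproducible.

## Coverage and RPM

`accumulateCoverage()` increments per-position depth on the placement's
strand, one unit per reported placement ("all" mode).  This
depth-from-all-alignments convention is what makes the two copies of a
mirror group show identical peak patterns; a `1/n_hits` fractional mode is
available for sensitivity analysis.  Reads-per-million is

> RPM\[i\] = depth\[i\] / (library size / 10^6)

with the **library total after trimming and filtering** as the default
denominator.  Mapping rates differ between samples, so normalizing by the
library total keeps profiles comparable; a mapped-read denominator is one
flag away (`denominator = "mapped"`) for users who prefer it.  Plus- and
minus-strand tracks are never mixed into a net track.

Cross-sample comparison (`compareProfiles()`) is deliberately scale-free:
absolute RPM differs by orders of magnitude between libraries while the
positional pattern is the conserved feature.  It reports the Spearman rank
correlation of per-position RPM over one element plus the overlap fraction
of top-decile positions (ties broken by coordinate so results are
deterministic).

## Region statistics and the MaskRNA call

`assignRegions()` attributes each placement to the element containing its
read-strand 5′ end.  The 5′ end, not majority overlap, is the assignment
coordinate for the same reason it anchors the aligner seed: piRNA-like
reads have sharply defined 5′ ends, and the first-nucleotide statistic is
defined on exactly that base.  A read whose 5′ end sits 1 nt outside an
element is unassigned no matter how much of its body overlaps; where
annotations overlap, the smallest containing element wins (the most
specific annotation), with coordinate order as the tie-break.  A
full-containment rule is available for sensitivity analysis.

`regionStrandStats()` emits, per (collapsed element, strand class): read
count, the length histogram over the bins 1–5 … 31–35, 36+ nt, mean
length, and first-base percentages over A/U/C/G (reads are DNA, so the
sequenced T is reported as U).  Empty cells keep count 0 with `NA`
percentages rather than propagating NaN.

`classifyMaskRNA()` applies the MaskRNA definition with its three criteria
split by their logical level: per read, (1) antisense to a targeted
element and (2) length within \[26, 30\] nt ("approximately 26–30" is
implemented as the closed interval, configurable); criterion (3),
"preferentially U", is a property of a population, not of any single read,
so it gates the element-level verdict: positive iff at least `minReads`
(default 50) flagged reads *and* a 5′-U fraction of at least
`minUFraction` (default 0.6) among them.  Both thresholds are explicit
configuration — nothing in the underlying biology fixes them — and the
defaults are chosen so that the contrast between silencing-positive
(hundreds of flagged reads) and silencing-negative (a handful) libraries
is decided by abundance, with the U gate excluding populations that merely
pass on count.

## Ping-pong signature

The ping-pong amplification loop produces sense/antisense read pairs whose
5′ ends overlap by exactly 10 nt.  `pingPongSignature()` tallies, within
one element, opposite-strand 5′-end pairs at overlap distances 1–20
(computed from the per-position 5′-end histograms, so it is quadratic in
distinct positions, not in reads) and standardizes the distance-10 count
against the other distances:

> z10 = (count\[10\] − mean(count\[d ≠ 10\])) / sd(count\[d ≠ 10\])

z10 is reported as undefined (`NA`) when either strand contributes no 5′
ends in the element or fewer than two other distances are informative.
Because positional hotspots concentrate both strands' reads, the null
distribution of pair counts is heavy-tailed and z10 values are modest even
for strongly paired libraries; the meaningful readout is the *contrast*
between libraries, which is what the test suite asserts (paired libraries
beat matched unpaired ones across 50 replicate seeds).

## The synthetic generator

`generateLibrary()` draws libraries with the statistical structure the
analysis assumes, plus a per-read ground-truth manifest:

| parameter | default | meaning |
|---|---|---|
| `elementWeights` | UTR 0.25, ORF 0.65, background 0.10 | fraction of reads per element; background reads are uniform over the reference with random strand |
| `antisenseFraction` | 0.90 | chance an element read is antisense to its element |
| `lengthProbs` | discretized normal, mean 28 nt, sd 1.5, on \[15, 40\] | read-length law; 26–30 nt mode |
| `u5Probability` | 0.874 | chance the 5′ base is forced to T |
| `hotspotK`, `hotspotSpread` | 5 hotspots, sd 3 nt | per-(element, strand-class) mixture from which 5′ positions are drawn |
| `pingpongFraction` | 0 | fraction of reads emitted as sense partners with an exact 10-nt 5′ overlap to a sampled antisense read |
| `errorRate` | 0.001/base | uniform substitution error, applied after 5′ forcing |
| `adapter`, `readCycles` | none, 50 | optional 3′ adapter; reads truncated to the cycle count as on a fixed-cycle sequencer |

The antisense fraction, 5′-U probability and mean length defaults are the
headline values of the dominant antisense read class in silencing-positive
ovary libraries; the hotspot count and spread are a modeling choice that
reproduces the strong positional concentration seen in real vector
profiles.  Hotspots are drawn separately per strand class (sense and
antisense reads arise from different precursors) and have their own seed
(`hotspotSeed`), so two libraries can share a hotspot layout while
sampling independent reads — the situation of two transgenic lines
producing antisense reads from the same reporter regions.

Two semantics are worth spelling out.  First, `u5Probability` *forces* the
5′ base: unforced reads keep the reference base, so the realized U
fraction is `p + (1 − p) × (reference T frequency)` (≈ 0.90 at the
default), and recovery is always judged against the manifest's realized
summaries, not the nominal probability.  Forcing only position 0 keeps
first-base bias isolated from background composition.  Second, the
generator is deterministic: a fixed spec yields byte-identical FASTQ and
manifest.

What the generator does **not** emulate: position-dependent error
profiles, quality-score structure (qualities are constant), ligation
biases, PCR duplicates, indels, and reads spanning a circular junction.
Passing tests on synthetic libraries therefore demonstrate correctness of
the accounting — alignment completeness, strand separation, normalization,
classification logic — not robustness to every artifact of real
small-RNA-seq chemistry.

## Numerical and scale choices

* Parameter-recovery checks run at 50,000 reads with weights only on
  annotated elements; estimates are required to fall within three
  binomial/standard errors of the manifest's realized values.  Background
  reads falling inside an element dilute element-level estimates by
  design (they are indistinguishable from signal), which is why the
  recovery condition is background-free.
* The MaskRNA verdict contrast uses 5,000-read libraries whose targeted
  5′-UTR antisense abundance is set to ≈ 350 and ≈ 7 flagged reads — the
  two regimes observed for silencing-positive vs silencing-negative
  transgenic lines — against the default `minReads = 50`.
* Ping-pong separation is asserted over 50 replicate seed pairs at 1,200
  reads per library.
* Oracle-equivalence checks for the aligner run on a 2 kb reference with
  200 reads and mismatch budgets 0–2.

These sizes are the package's own validation conditions; all are
regenerated in code at test time.

## Known limitations

* Ungapped alignment only; references beyond a few tens of kilobases will
  index fine but the aligner is not engineered for genome-scale use.
* The MaskRNA verdict thresholds are operating points, not estimates; on
  real libraries they should be read as a reporting convention and varied.
* z10 has no calibrated null here — it is a contrast statistic, and its
  absolute value depends on the positional concentration of the library.
* Copy-group collapsing assumes exact copy identity; near-identical copies
  (one divergent base) are deliberately left uncollapsed and will split
  read counts between copies.
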