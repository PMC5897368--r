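Package: maskRNAprofiler
Title: Strand-Specific Profiling of piRNA-Like Small RNAs over Transgene Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes piRNA-like small RNAs (MaskRNAs) from small-RNA
    sequencing libraries mapped to annotated transgene vector references.
    Provides adapter trimming and length filtering, an exact ungapped
    seed-and-verify short-read aligner with multi-hit reporting,
    strand-separated per-nucleotide depth and reads-per-million (RPM)
    coverage tracks, region- and strand-stratified length and
    first-nucleotide statistics, MaskRNA classification (antisense,
    26-30 nt, 5' uridine bias), a ping-pong 10-nt 5' overlap signature,
    cross-sample positional profile comparison, and a deterministic
    synthetic small-RNA library generator with a ground-truth manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
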