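Package: polterm
Title: Stochastic RNA Polymerase I Transcription with Premature Termination
    and Nascent-Transcript End Profiling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lattice model of RNA polymerase I transcription on the rDNA:
    Brownian-ratchet elongation biased by nascent-RNA folding and by torsional
    entrainment between co-transcribing polymerases, with a position-limited
    premature-termination hazard. Includes parameter-grid experiments relating
    the premature-termination probability to per-generation ribosome output,
    a synthetic generator for CRAC-like aligned reads over an rDNA-like
    reference, nucleotide-resolution 5'/3'-end profiling with unit
    normalization and Blackman smoothing, oligo(A) tail selection, peak
    calling with peak-anchored metaplots, readthrough statistics, and a
    rolling-window nascent-RNA folding-energy track.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
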