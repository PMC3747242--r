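Package: dimorphseq
Title: Sexually Dimorphic Transcription-Factor Occupancy from Paired ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls sexually dimorphic transcription-factor regulation from
    paired (male/female) ChIP-seq experiments. Implements a signed, log-scaled
    two-sample Poisson score for binding-site read counts in a window around
    each peak summit, an RNA polymerase II gene-body occupancy score from the
    transcription start to the transcription end site, interval rules for
    common/unique peak classification and peak-to-gene assignment, and the
    integration of both chromatin scores with expression fold-changes into
    per-gene dimorphism calls. Ships a synthetic-data generator that plants
    dimorphic structure with a machine-readable truth table so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
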