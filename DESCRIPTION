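Package: cagegrn
Title: Enhancer Gene Regulatory Networks from Bidirectional CAGE-Seq Transcription
Version: 0.1.0
Authors@R:
    person("Merel", "Jansen", email = "merel.jansen@example.org",
           role = c("aut", "cre"))
Description: Calls candidate enhancers from CAGE-seq 5' tag data via
    bidirectional transcription, predicts transcription factor binding at
    those enhancers with a logistic model combining motif z-scores, enhancer
    intensity and curated ChIP-seq coverage, infers TF-to-gene regulatory
    networks, and ranks transcription factors by an influence score that
    explains the transition between two cell states.  Includes a
    deterministic synthetic-data generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
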