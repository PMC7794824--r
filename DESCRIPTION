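Package: mimscout
Title: Discovery and Context Evaluation of MYC-Interaction Motifs in Plant
    Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering the short linear MYC-interaction motif
    (MIM) in protein sequences and for evaluating candidate occurrences.
    Provides degenerate-pattern scanning, position-specific scoring-matrix
    search with empirical E-values and iterative query refinement,
    sliding-window compositional profiling of the disordered sequence
    context around a hit, alignment-column conservation contrasts with a
    permutation null, and estimation of transient helicity from Calpha
    secondary chemical shifts.  A synthetic-data module generates
    proteomes with planted motifs, alignments with controlled column
    conservation, and chemical-shift tables with known helicity, so the
    whole pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
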