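Package: chirpscreen
Title: Concordance-Based ChIRP-seq Peak Analysis and qPCR Screening for
    Chromatin-Associated lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterizing the chromatin occupancy of a
    long non-coding RNA from ChIRP-seq (chromatin isolation by RNA purification
    sequencing) even/odd probe lanes, together with the efficiency-corrected
    qPCR screen used to nominate cancer-stem-cell-enriched lncRNA candidates.
    Provides per-base coverage-track operations (blacklist masking, even/odd
    consensus by per-base minimum, depth normalization), a transparent
    local-Poisson peak caller with the multi-criteria peak filter (fold
    enrichment, average coverage, even/odd Pearson concordance), genic peak
    annotation, regulated-gene-set derivation and hypergeometric/Fisher
    enrichment statistics, summit-window extraction for motif discovery, and a
    seeded synthetic-data module that generates every input with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
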