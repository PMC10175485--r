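Package: uvhotspot
Title: UV Damage Hotspots at Transcription-Factor Binding Sites from
    CPD-Capture-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of targeted UV-damage sequencing (CPD-capture-seq) data:
    calls putative cyclobutane pyrimidine dimer (CPD) lesions from aligned read
    positions with dipyrimidine filtering, scales naked-DNA controls, computes
    per-site damage-induction profiles and Z-scores at transcription-factor
    binding sites, screens hexamer sequence contexts for binding-associated
    damage, fits a Poisson regression of recurrent somatic mutation counts on
    cellular and naked-DNA CPD counts, measures trinucleotide-context mutation
    enrichment and accessibility correlations, and classifies recurrent
    mutation sites as likely passengers or candidate drivers. Includes a
    synthetic-data generator that emulates the statistical structure of the
    real libraries so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
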