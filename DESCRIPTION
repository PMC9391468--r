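Package: thymotif
Title: Allele-Specific Motif Disruption in Thymocyte Active Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers DNA sequence motifs in histone-modification peak
    regions with overlapping RNA expression (active chromatin), builds
    chromatin pseudostates by interval intersection, scans reference and
    alternative allele flanking sequences of credible-set variants (SNVs
    and indels) against the discovered motifs with exact null p-values,
    and tests allelic differences with an empirical z-score E-value
    statistic (E_diff). A parallel arm scores biophysical transcription
    factor affinity (TRAP-style) with empirical-null p-values. Ships a
    synthetic-data generator producing a full plain-text input bundle
    (genome, exons, peaks, coverage, variants) with known truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
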