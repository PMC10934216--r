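Package: ssrscape
Title: Microsatellite Mining and Cross-Sample Classification for
    Target-Enrichment Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines perfect and compound microsatellites (SSRs, 1-6 bp
    motifs) from per-locus multiple sequence alignments of nuclear exons
    and their flanking regions, using MISA-compatible minimum-repeat
    thresholds and a strict zero-interruption definition of compound
    repeats. Alignment gaps are stripped with an invertible coordinate
    map, so repeats detected on degapped sequences can be compared
    across samples in alignment-column space and classified as unique,
    shared, or repeat-count polymorphic at the species, genus, or
    across-genera tier. Includes compound-repeat normalization (minimal
    re-segmentation and motif-phase consensus), density and composition
    summaries, primer-template extraction with Boulder-IO output, and a
    synthetic-alignment generator that plants repeats of known category
    with a ground-truth ledger for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
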