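Package: varburden
Title: Rare-Variant Filtration, Case-Control Burden and Gene-Level
    Recurrence for Germline Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-stage filtration of annotated germline variant calls
    (VQSLOD pass, exonic/splice-site location, depth, alt-read support,
    variant allele fraction, population minor allele frequency, and
    cohort-recurrence artifact removal), restriction to a virtual panel
    of cancer-associated genes, PolyPhen-2 triage of missense variants,
    extraction of protein-damaging allelic variants (nonsense,
    frameshift, splice-site, stop-loss), per-sample per-category burden
    comparison between cases and controls (Student and Welch t-tests
    with fold-change ratios), and gene-level recurrence candidate
    selection. Includes a seeded synthetic-cohort generator so every
    stage is testable without access to raw exomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
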