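Package: trioscope
Title: Trio-Based De Novo Mutation Discovery, Validation, Phasing and
    Postzygotic Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for trio-based de novo mutation (DNM)
    analysis from multi-platform sequencing evidence: naive candidate
    selection from trio VCFs, three-platform read-evidence validation
    (PacBio HiFi, Oxford Nanopore, Illumina), cohort recurrence and
    repeat-context filters, parent-of-origin phasing by informative SNPs
    with an inverse-distance read inheritance score, germline versus
    postzygotic classification from per-haplotype read counts and
    cross-platform allele balance, callable-genome accounting with
    mutation-rate estimation, and mutation-spectrum statistics
    (Ti/Tv, parental-age regression, parent-of-origin ratios,
    multinucleotide-mutation pairs). Includes a calibrated synthetic
    trio-cohort generator with truth tables so every stage is testable
    without access to raw sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
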