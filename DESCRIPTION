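Package: snvguide
Title: Allele-Specific CRISPR/Cas9 Guide Design Against Passenger SNVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies somatic passenger single-nucleotide variants (SNVs) in
    essential or haploinsufficient genes that admit allele-specific,
    high-efficiency, low-off-target SpCas9 single-guide RNAs, and summarizes
    patient eligibility across a cancer cohort. Implements per-sample variant
    quality and clonality filtering (a median + MAD allele-frequency
    threshold), gene-class and expression filters, enumeration of
    allele-discriminating protospacer/PAM placements on both strands,
    pluggable on-target scoring, exhaustive mismatch-tolerant off-target
    scanning with Cutting Frequency Determination (CFD) scoring, eligibility
    aggregation, T7E1 editing-readout math, and a deterministic synthetic
    cohort generator (genome, MAF, expression, catalogs) with planted ground
    truth for end-to-end testing.
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
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
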