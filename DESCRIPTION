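Package: drgfpScreen
Title: Hit Calling and Phenotype Classification for DR-GFP Homologous
    Recombination RNAi Screens
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for genome-scale RNAi screens that use the
    DR-GFP reporter to measure homologous-recombination-mediated repair of
    DNA double-strand breaks. Implements 384-well plate-based z-score
    normalization (per-plate and negative-control-based), dual
    silencing-trigger hit validation, GFP-level counterscreen and viability
    exclusion filters, graded secondary-assay phenotype classification
    (drug/IR sensitivity, gamma-H2AX kinetics), hypergeometric category
    enrichment, AP-MS background filtering, and coding-indel frameshift
    annotation. A seeded synthetic-screen generator with ground truth
    emulates the FACS percent-GFP-positive readout so the whole pipeline
    is testable without raw flow-cytometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
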