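Package: nscquant
Title: Quantification of Cell-Cycle Exit and Transcription-Factor Dosage in
    Neural Progenitor Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify cell-cycle exit and transcription-factor
    dosage in adult neural stem/progenitor cell cultures. Implements a
    CDK2-activity bioimage workflow for the DHB-mVenus kinase translocation
    reporter (nuclear and whole-cell segmentation, removal of
    reporter-negative cells, seeded Voronoi separation of touching cells,
    cytoplasm derivation by mask subtraction, cytoplasm/nucleus ratio
    computation and G0/G1 classification), per-cell nuclear-marker intensity
    profiling (max-normalized frequency histograms, medians, percent-positive
    and top-fraction "high" calls), comparative-Ct quantification of
    ChIP-qPCR enrichment against a non-related antibody with a
    dilution-series positivity rule, dual-luciferase reporter ratios, and an
    ATAC-seq x RNA-seq integration that assigns accessibility peaks to gene
    promoters and labels genes into joint regulation categories. Seeded
    synthetic-data generators provide ground-truthed microscopy fields, Ct
    tables and gene/peak tables so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
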