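Package: gtlkit
Title: Spectral Library Construction and Retention-Time Calibration for DIA Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the bespoke computational stages of a
    data-independent-acquisition (DIA) proteomics workflow: building
    OpenSWATH-compatible generic transition lists (GTL) from consensus DDA
    spectra, iterative selection of endogenous retention-time anchor
    peptides with a lasso calibration model, combination of peptide
    quantifications searched against multiple spectral libraries,
    correlation-clique protein summarization of peptide quantification
    matrices, and RNA-guided construction of single-amino-acid-variant
    (SAAV) and isoform-aware peptide libraries. Includes seeded synthetic
    data generators that emulate every required input with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    glmnet,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
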