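Package: neopred
Title: Peptide-MHC Binding, Neoantigen Load and Immune-Evasion Prediction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling tumour immunogenicity from somatic
    mutations. Derives 20x20 amino-acid contact potentials from protein
    structures, encodes peptide-HLA pairs as two-dimensional interaction
    maps, trains a small convolutional neural network to classify
    peptide-MHC class I binding, enumerates mutant peptides to estimate
    per-sample neoantigen load, classifies therapeutic resistance from
    functional-mutation profiles with a seeded random forest and a
    synonymous-mutation negative control, and relates immune-evasion
    status to resistance parameters with regularized regression. Seeded
    synthetic-data generators with planted signal make the full pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
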