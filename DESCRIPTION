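Package: dephossite
Title: Phosphatase-Specific Tyrosine Dephosphorylation Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts substrate dephosphorylation sites of the protein
    tyrosine phosphatases PTP1B, SHP-1 and SHP-2 from peptide windows
    centered on tyrosine residues. Implements a position-weighted BLOSUM62
    similarity scorer whose per-position weights are trained by AUC-driven
    hill climbing (MGPS), a support vector machine on the composition of
    k-spaced amino acid pair (CKSAAP) encoding, and a BLOSUM62 k-nearest
    neighbour baseline, together with dataset construction (window
    extraction, redundancy reduction), jackknife and repeated k-fold
    evaluation with ROC/AUC and fixed-specificity operating points,
    per-position Fisher's exact enrichment analysis, predictor
    complementarity and a linear-SVM ensemble, and a synthetic
    motif-dataset generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
biocViews: SequenceMatching, Classification, SupportVectorMachine,
    Proteomics, PostTranslationalModification
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
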