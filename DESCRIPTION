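Package: ContactLadder
Title: Benchmarking Evolutionary Residue Contact Predictors Across a
    Distance-Cutoff Ladder
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates residue-residue contact predictions derived from
    evolutionary signals (correlated mutations, sequence variability,
    Shannon entropy, compression-based Kolmogorov complexity, and
    residue-pair likelihood matrices) against CA-CA contact maps computed
    from protein structures at a ladder of distance cutoffs. Provides
    per-column alignment conservation scores, range-based pair predictors,
    confusion-matrix statistics (Matthews correlation coefficient,
    accuracy, precision, sensitivity) with random-baseline correction,
    score-range calibration, characteristic-contact-distance peak
    extraction, cross-method principal component analysis, and a coupled
    structure/alignment synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Proteomics, StructuralPrediction, Alignment, Software
RoxygenNote: 7.3.3
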