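Package: vemap
Title: Variant-Effect Map Scoring, Analysis and Clinical Calibration for
    Multiplexed Assays of Variant Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning multiplexed variant-effect screen sequencing
    counts (TileSeq-style growth selections and VAMP-seq-style abundance
    sorts) into rescaled functional score maps, and for downstream biological
    and clinical analysis of those maps. Implements wild-type-control error
    correction of enrichment ratios, rescaling to nonsense/synonymous
    anchors, delta-method error propagation with empirical error
    regularization, and inverse-variance replicate averaging. Provides joint
    dual-map quadrant classification, positional and substitution profiles,
    annotation-group contrasts, stability (ddG) concordance, population
    depletion odds ratios, and genotype-phenotype correlation. Converts
    scores into log likelihood ratios of pathogenicity via Epanechnikov
    kernel density estimation with Sheather-Jones bandwidth, benchmarked by
    balanced precision-recall (AUBPRC, R80BP) and calibrated to ACMG/AMP
    evidence strengths. Includes a seeded synthetic-screen generator
    modelling NNK saturation mutagenesis libraries so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
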