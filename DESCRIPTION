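Package: CogTx
Title: Transcriptome Screens Linking Brain Aging to Cognitive Flexibility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for bulk RNA-seq studies that relate
    regional brain gene expression to aging and to prefrontal-dependent
    set-shift behavior in rats. Provides gene filtering, median-of-ratios
    normalization, per-gene age-effect screening, gene-wise Pearson
    correlation of expression with behavioral trials-to-criterion scores
    using analytic critical-r thresholds, cross-study directional
    concordance testing with an expected-direction false discovery rate,
    a composite z-score gene-set index, impaired/unimpaired mean-split
    classification, water-maze discrimination-index and delta-delta-Ct
    arithmetic, spike-in linearity QC, and a negative-binomial count
    simulator with planted age and behavior effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, DESeq2, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
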