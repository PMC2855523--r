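Package: tldaRQ
Title: Relative Quantification and Class Analysis of TaqMan Low Density
    Array miRNA Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of cycle-threshold (CT) data from TaqMan
    low density array (TLDA) microRNA profiling experiments. Implements
    delta-delta-Ct relative quantification against an endogenous control
    (MammU6) and a calibrator sample, class-comparison statistics with
    random-variance moderated t-tests, Benjamini-Hochberg and
    confidence-bounded multivariate-permutation false discovery control,
    multidimensional scaling and Eisen-style hierarchical clustering of
    expression profiles, and multi-classifier class prediction with nested
    leave-one-out cross-validation. Includes a synthetic CT data generator
    that emulates a two-panel 666-assay melanoma profiling design with
    planted fold-change effects, so every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
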