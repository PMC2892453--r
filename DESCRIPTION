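Package: flumir
Title: MiRNA Expression Markers of Fludarabine Response in Chronic
    Lymphocytic Leukemia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for discovering and applying microRNA markers
    of fludarabine resistance in chronic lymphocytic leukemia (CLL) from
    single-channel miRNA microarray and RT-qPCR data. Implements array
    preprocessing (negative-value flooring, quantile normalization, log2
    transform, presence filtering), two-group differential expression based
    on fold changes of geometric means with Welch t-tests and optional
    Benjamini-Hochberg adjustment, Venn intersection of marker lists,
    complete-linkage hierarchical clustering of samples with two-group
    classification accuracy, matched pre/post percentile modulation filters,
    comparative-Ct (2^-deltaCt) quantification of qPCR data, a three-miRNA
    percentile-threshold predictive score for treatment response, and
    hypergeometric over-representation analysis against user-supplied gene
    sets. A synthetic-cohort generator with planted effect sizes makes every
    stage testable end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
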