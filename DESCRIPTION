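Package: syndromefuse
Title: Network-Fusion Multi-Omics Biomarker Discovery for Disease Syndrome Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative network-fusion pipeline for discriminating
    clinically defined disease syndrome subtypes (e.g. Cold- and Hot-pattern
    rheumatoid arthritis) from multi-omics abundance data.  Provides a
    synthetic multi-omics cohort simulator with a fully known planted
    evidence chain, univariate differential screening (Mann-Whitney rank
    test, fold change, Benjamini-Hochberg adjustment), PCA and NIPALS
    PLS-DA with cross-validated component selection and VIP scoring,
    disease-syndrome-symptom association network construction with
    centrality-based key-target selection, hypergeometric pathway
    over-representation, gene-metabolite network fusion with composite
    biomarker ranking, and ROC / confusion-matrix validation of candidate
    biomarkers on held-out cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
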