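Package: tnbcmodules
Title: Molecular Phenotyping of Triple-Negative Breast Cancer Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for molecular phenotyping of triple-negative
    breast cancer (TNBC) cohorts profiled on degraded FFPE material.
    Implements detection-based quality control for WG-DASL-style microarray
    data (sample/probe detection filters, an exact longest-run test for
    slide-batch dropout artifacts, outlier-masked quantile normalization),
    unsupervised module discovery by PCA with Fisher and GO-elim gene-set
    enrichment, gene-signature activation scoring by Pearson correlation with
    stage-stratified permutation inference and FDR control, VEGF rank
    profiling, k-means detection of luminal androgen receptor (LAR) high
    samples, and AQUA-style microvessel-area quantification of multi-channel
    tissue-microarray histospots. A synthetic-data module generates
    expression cohorts, count matrices and histospot images with known
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
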