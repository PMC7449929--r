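Package: glutTME
Title: Reciprocal Glucose Metabolism of Cancer and Immune Cells in the
    Tumor Microenvironment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying competitive glucose uptake between cancer
    and immune cells from bulk transcriptomes, single-cell RNA-seq and
    FDG-PET imaging. Implements single-sample gene-set enrichment (ssGSEA)
    scoring with an immune-cell ImmuneScore summation, kernel-density
    based stratification of cohorts into immune-rich and immune-poor
    clusters, adaptive-threshold quantification of PET uptake volumes
    (TLRmax, metabolic tumor volume), GLUT1/GLUT3 gating of single cells,
    and the GLUT3/GLUT1 ratio as an immunotherapy-response biomarker with
    response-group and survival analyses. Ships seeded synthetic-cohort
    generators that emulate the assumed data structure so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    survival,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, SingleCell, GeneSetEnrichment, Survival
RoxygenNote: 7.3.3
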