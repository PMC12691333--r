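Package: habikit
Title: Habitat Radiomics for Tumor Subregion Analysis on CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Habitat-based radiomics analysis of 3D tumor volumes: per-voxel
    intensity/entropy feature maps, population-level k-means clustering into
    tumor subregions ("habitats") with Calinski-Harabasz model selection,
    filter-bank texture-feature extraction (first-order, GLCM, GLRLM, GLSZM,
    GLDM, NGTDM, shape) for whole tumors and each habitat, stability and
    redundancy filtering with mRMR and LASSO feature selection, radiomics-score
    construction, and logistic prediction models compared by DeLong's test,
    with calibration and decision-curve analysis. Ships a seeded synthetic
    phantom-cohort generator with planted habitat structure so the entire
    pipeline is testable end to end without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
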