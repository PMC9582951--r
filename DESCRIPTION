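Package: radiopathomics
Title: Cross-Scale Association of Radiomic and Pathomic Image Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying cross-scale associations between quantitative
    imaging features of tumours at the radiological and the histopathological
    scale. Provides a 91-feature intensity/texture engine (first-order, GLCM,
    GLRLM, GLSZM, GLDM, NGTDM) applicable to 3D MRI volumes inside a volume of
    interest and to 2D nuclear cell-density maps built from digitised-pathology
    cell detections at multiple spatial resolutions; per-cell Delaunay spatial
    statistics and slide-level aggregation of detection measurements;
    redundancy filtering, Spearman correlation screening with
    Benjamini-Hochberg false-discovery-rate control and correlation Bayes
    factors; and ridge-regularised maximum-likelihood factor analysis with
    varimax rotation, Thomson regression scores and factor-score
    cross-correlation. A seeded synthetic-cohort generator with a planted
    latent coupling between the pathology and radiology blocks supports
    power, calibration and recovery experiments end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    interp,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    caret,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
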