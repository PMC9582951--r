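#' Feature name registries
#'
#' The texture engine emits a fixed, ordered set of 91 named features:
#' 18 first-order intensity statistics plus 73 texture features from five
#' gray-level matrix families (22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
#' 5 NGTDM). Names follow the IBSI / common radiomics nomenclature so that
#' downstream association tables read naturally (e.g. `glszm_LargeAreaLowGrayLevelEmphasis`,
#' abbreviated LALGLE in the literature).
#'
#' @name feature_names
NULL

rp_firstorder_names <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"
)

rp_glcm_names <- c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
  "MaximumProbability", "SumEntropy", "SumSquares"
)

rp_glrlm_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis"
)

rp_glszm_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis"
)

rp_gldm_names <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis"
)

rp_ngtdm_names <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

rp_feature_classes <- c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm")

rp_class_names <- function(class) {
  switch(class,
    firstorder = rp_firstorder_names,
    glcm = rp_glcm_names,
    glrlm = rp_glrlm_names,
    glszm = rp_glszm_names,
    gldm = rp_gldm_names,
    ngtdm = rp_ngtdm_names,
    rp_abort("unknown feature class: ", class)
  )
}

#' Names of the full 91-feature vector
#'
#' @param classes Feature classes to include, in fixed canonical order.
#' @param prefix Optional block prefix (e.g. `"ADC"`, `"CD200um"`) prepended
#'   with an underscore.
#' @return Character vector of feature names, `class_Name` style.
#' @export
#' @examples
#' length(rp_feature_names()) # 91
rp_feature_names <- function(classes = rp_feature_classes, prefix = NULL) {
  classes <- match.arg(classes, rp_feature_classes, several.ok = TRUE)
  classes <- rp_feature_classes[rp_feature_classes %in% classes]
  nms <- unlist(lapply(classes, function(cl) paste(cl, rp_class_names(cl), sep = "_")),
                use.names = FALSE)
  if (!is.null(prefix)) nms <- paste(prefix, nms, sep = "_")
  nms
}

# ---------------------------------------------------------------------------
# Per-cell detection measurement schema (65 columns)
# ---------------------------------------------------------------------------

rp_shape_names <- c(
  "Nucleus: Area", "Nucleus: Perimeter", "Nucleus: Circularity",
  "Nucleus: Max caliper", "Nucleus: Min caliper", "Nucleus: Eccentricity",
  "Nucleus/Cell area ratio"
)

rp_intensity_names <- local({
  comp <- c("Nucleus", "Cytoplasm", "Cell")
  stain <- c("Hematoxylin", "Eosin", "ODSum")
  stat <- c("Mean", "Std.Dev.", "Min", "Max")
  as.vector(t(outer(
    as.vector(t(outer(comp, stain, paste, sep = ": "))),
    stat, paste, sep = " OD "
  )))
})

rp_haralick_names <- paste(
  "Haralick",
  c("ASM", "Contrast", "Correlation", "SumOfSquares", "IDM", "SumAverage",
    "SumVariance", "SumEntropy", "Entropy", "DiffVariance", "DiffEntropy",
    "IMOC1", "IMOC2"),
  paste0("F", 0:12)
)

rp_delaunay_names <- c(
  "Delaunay: Num neighbors", "Delaunay: Mean distance",
  "Delaunay: Median distance", "Delaunay: Min distance",
  "Delaunay: Max distance", "Delaunay: Mean triangle area",
  "Delaunay: Max triangle area", "Delaunay: Cluster size",
  "Delaunay: Distance to cluster centroid"
)

#' The per-cell detection measurement schema
#'
#' Ordered names of the 65 measurements carried by every cell detection row:
#' 7 nuclear shape descriptors, 36 staining-intensity statistics
#' (\{Nucleus, Cytoplasm, Cell\} x \{Hematoxylin, Eosin, ODSum\} x
#' \{mean, SD, min, max\}), 13 intranuclear Haralick texture features on the
#' optical-density sum, and 9 Delaunay spatial-neighbourhood measurements.
#'
#' @return Named list with elements `shape`, `intensity`, `haralick`,
#'   `delaunay` and `all` (the 65 names in order).
#' @export
#' @examples
#' length(rp_detection_schema()$all) # 65
rp_detection_schema <- function() {
  list(
    shape = rp_shape_names,
    intensity = rp_intensity_names,
    haralick = rp_haralick_names,
    delaunay = rp_delaunay_names,
    all = c(rp_shape_names, rp_intensity_names, rp_haralick_names, rp_delaunay_names)
  )
}

# Centroid / slide columns used by the detection TSV dialect
rp_centroid_cols <- c("Slide", "Centroid X \u00b5m", "Centroid Y \u00b5m")
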