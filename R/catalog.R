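.HISTOGRAM_NAMES <- c("Energy", "Entropy", "Uniformity", "Mean",
                      "Variance", "Skewness", "Kurtosis", "Minimum",
                      "Maximum", "Range")
.GLCM_NAMES <- c("GAutocorrelation", "GClusterProminence", "GClusterShade",
                 "GClusterTendency", "GContrast", "GCorrelation",
                 "GDifferenceEntropy", "GDissimilarity", "GEnergy",
                 "GEntropy", "GHomogeneity1", "GHomogeneity2", "GIMC1",
                 "GIMC2", "GIDMN", "GIDN", "GInverseVariance",
                 "GMaxProbability", "GSumAverage", "GSumEntropy",
                 "GSumVariance", "GVariance")
.GLRLM_NAMES <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                  "SRLGE", "SRHGE", "LRLGE", "LRHGE")
.GLSZM_NAMES <- c("SZE", "LZE", "ZGLN", "ZSN", "ZP", "LGZE", "HGZE",
                  "SZLGE", "SZHGE")
.SHAPE_NAMES <- c("volume", "surface_area", "surface_to_volume_ratio",
                  "sphericity", "compactness1", "compactness2",
                  "spherical_disproportion", "max_3d_diameter")
.SHAPE_IDS <- c("ShapeVolume", "ShapeSurfaceArea",
                "ShapeSurfaceToVolumeRatio", "ShapeSphericity",
                "ShapeCompactness1", "ShapeCompactness2",
                "ShapeSphericalDisproportion", "ShapeMax3DDiameter")

#' The 476-feature catalog
#'
#' Eight shape features from the mask plus, for each of the 9 component
#' images (ROI and the 8 wavelet subbands), 10 histogram features and
#' 42 texture features (22 GLCM, 11 GLRLM, 9 GLSZM):
#' `8 + 9 x (10 + 42) = 476`. Feature ids concatenate the component and
#' the feature name, with GLCM names carrying a `G` prefix (e.g.
#' `LLLEnergy`, `ROIGCorrelation`, `HLLLRE`, `HHLZP`). The GLSZM
#' gray-level non-uniformity is id'd `ZGLN` to keep ids unique against
#' the GLRLM `GLN`.
#'
#' @return data.frame with columns `id`, `component`, `family`, `name`.
#' @export
featureCatalog <- function() {
  shape <- data.frame(id = .SHAPE_IDS,
                      component = "Shape", family = "shape",
                      name = .SHAPE_NAMES)
  per_comp <- do.call(rbind, lapply(.WAVELET_COMPONENTS, function(cmp) {
    rbind(
      data.frame(id = paste0(cmp, .HISTOGRAM_NAMES), component = cmp,
                 family = "histogram", name = .HISTOGRAM_NAMES),
      data.frame(id = paste0(cmp, .GLCM_NAMES), component = cmp,
                 family = "glcm", name = .GLCM_NAMES),
      data.frame(id = paste0(cmp, .GLRLM_NAMES), component = cmp,
                 family = "glrlm", name = .GLRLM_NAMES),
      data.frame(id = paste0(cmp, .GLSZM_NAMES), component = cmp,
                 family = "glszm", name = .GLSZM_NAMES))
  }))
  out <- rbind(shape, per_comp)
  rownames(out) <- NULL
  stopifnot(nrow(out) == 476L, !anyDuplicated(out$id))
  out
}

#' Write the feature catalog as JSON
#'
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCatalogJson <- function(path) {
  jsonlite::write_json(featureCatalog(), path, digits = NA)
  invisible(path)
}
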