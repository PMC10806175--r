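#' CTVolume: a 3D CT image with physical geometry
#'
#' Container for a scalar 3D image in Hounsfield units together with its
#' voxel spacing and world origin. World coordinate of voxel index
#' `(i, j, k)` (0-based) is `origin + c(i, j, k) * spacing`.
#'
#' @slot voxels 3D numeric array of intensities (HU for the native image;
#'   wavelet subbands are on their own scale).
#' @slot spacing numeric(3), voxel spacing in mm, all > 0.
#' @slot origin numeric(3), world position of voxel (0, 0, 0) in mm.
#'
#' @aliases CTVolume
#' @exportClass CTVolume
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("CTVolume", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3L)
    msgs <- c(msgs, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite values (mm)")
  if (any(!is.finite(object@voxels)))
    msgs <- c(msgs, "intensities must be finite")
  if (length(msgs)) msgs else TRUE
})

#' VOIMask: a binary tumor volume-of-interest mask
#'
#' Binary (0/1) mask on the same grid as its companion [CTVolume-class].
#' At least one foreground voxel is required.
#'
#' @slot voxels 3D integer array with values in {0, 1}.
#' @slot spacing numeric(3), mm.
#' @slot origin numeric(3), mm.
#'
#' @aliases VOIMask
#' @exportClass VOIMask
setClass("VOIMask",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("VOIMask", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3L)
    msgs <- c(msgs, "mask must be a 3D array")
  if (!all(object@voxels %in% c(0, 1)))
    msgs <- c(msgs, "mask values must be 0/1")
  if (sum(object@voxels) < 1)
    msgs <- c(msgs, "mask must contain at least one foreground voxel")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive values (mm)")
  if (length(msgs)) msgs else TRUE
})

#' QuantizedVolume: fixed-bin-width requantized intensities
#'
#' Gray levels `1..Ng` assigned to in-mask voxels by
#' `floor((I - min_in_mask) / bin_width) + 1`; voxels outside the mask
#' are `NA`.
#'
#' @slot levels 3D integer array, `NA` outside the mask.
#' @slot binWidth bin width on the image's intensity scale (HU for the
#'   native image), default 25.
#' @slot nLevels number of gray levels Ng.
#' @slot intensityMin in-mask minimum used as the bin anchor.
#'
#' @aliases QuantizedVolume
#' @exportClass QuantizedVolume
setClass("QuantizedVolume",
  representation(levels = "array", binWidth = "numeric",
                 nLevels = "integer", intensityMin = "numeric"))

setValidity("QuantizedVolume", function(object) {
  lv <- object@levels[!is.na(object@levels)]
  msgs <- character()
  if (!length(lv)) msgs <- c(msgs, "no in-mask levels")
  else if (min(lv) < 1 || max(lv) > object@nLevels)
    msgs <- c(msgs, "in-mask levels must lie in [1, Ng]")
  if (object@binWidth <= 0) msgs <- c(msgs, "binWidth must be > 0")
  if (length(msgs)) msgs else TRUE
})

.WAVELET_COMPONENTS <- c("ROI", "LLL", "LLH", "LHL", "LHH",
                         "HLL", "HLH", "HHL", "HHH")

#' WaveletBank: the 9 component images of a case
#'
#' The original (ROI) image plus the 8 subbands of a single-level
#' undecimated 3D wavelet transform. All components share the input grid
#' (the transform is stationary, so subbands stay in register with the
#' VOI mask). Subband names give the filter applied along (x, y, z):
#' `LLH` is low-pass in x and y, high-pass in z.
#'
#' @slot components named list of 9 arrays, names
#'   ROI, LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH.
#' @slot basis wavelet basis tag ("coif1" or "haar").
#' @slot spacing,origin grid geometry shared by all components.
#'
#' @aliases WaveletBank
#' @exportClass WaveletBank
setClass("WaveletBank",
  representation(components = "list", basis = "character",
                 spacing = "numeric", origin = "numeric"))

setValidity("WaveletBank", function(object) {
  msgs <- character()
  if (!identical(names(object@components), .WAVELET_COMPONENTS))
    msgs <- c(msgs, "components must be exactly ROI + the 8 subbands, in order")
  dims <- lapply(object@components, dim)
  if (length(unique(dims)) != 1L)
    msgs <- c(msgs, "all components must share one grid")
  if (length(msgs)) msgs else TRUE
})

#' ResponseModel: a trained CRT-response classifier
#'
#' Wraps one of the five supported algorithms together with everything
#' needed to score new cases reproducibly: the feature ids it was
#' trained on, the training-cohort standardization parameters, and the
#' seed.
#'
#' @slot algorithm one of "RF", "NB", "RR", "ANN", "SVM".
#' @slot fit the underlying fitted object.
#' @slot featureIds character vector of feature ids used.
#' @slot center,scale per-feature training mean / sd (z-scoring applied
#'   for RR, ANN and SVM; identity for RF and NB).
#' @slot seed integer seed used at fit time.
#'
#' @aliases ResponseModel
#' @exportClass ResponseModel
setClass("ResponseModel",
  representation(algorithm = "character", fit = "ANY",
                 featureIds = "character", center = "numeric",
                 scale = "numeric", seed = "integer"))

setValidity("ResponseModel", function(object) {
  if (!object@algorithm %in% c("RF", "NB", "RR", "ANN", "SVM"))
    return("algorithm must be one of RF, NB, RR, ANN, SVM")
  TRUE
})
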