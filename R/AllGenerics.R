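#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @export
setGeneric("componentImage", function(x, name) standardGeneric("componentImage"))

#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))

#' @export
setGeneric("algorithm", function(x) standardGeneric("algorithm"))

#' Accessors for image containers
#'
#' `voxelData()` returns the raw array, `voxelSpacing()` the mm spacing,
#' `voxelOrigin()` the world origin; `nLevels()` the number of gray
#' levels of a [QuantizedVolume-class]; `componentImage()` /
#' `componentNames()` address a [WaveletBank-class]; `algorithm()` the
#' algorithm tag of a [ResponseModel-class].
#'
#' @param x the object.
#' @param name component name (e.g. "LLL").
#' @return the addressed slot content.
#' @name accessors
#' @aliases voxelData voxelSpacing voxelOrigin nLevels componentImage
#'   componentNames algorithm
NULL

#' @rdname accessors
#' @export
setMethod("voxelData", "CTVolume", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("voxelData", "VOIMask", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("voxelData", "QuantizedVolume", function(x) x@levels)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VOIMask", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "WaveletBank", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "CTVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "VOIMask", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("nLevels", "QuantizedVolume", function(x) x@nLevels)
#' @rdname accessors
#' @export
setMethod("componentImage", "WaveletBank", function(x, name) {
  if (!name %in% names(x@components))
    stop("unknown component: ", name)
  x@components[[name]]
})
#' @rdname accessors
#' @export
setMethod("componentNames", "WaveletBank", function(x) names(x@components))
#' @rdname accessors
#' @export
setMethod("algorithm", "ResponseModel", function(x) x@algorithm)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "VOIMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VOIMask %d x %d x %d voxels, %d foreground (%.1f mm3)\n",
              d[1], d[2], d[3], sum(object@voxels),
              sum(object@voxels) * prod(object@spacing)))
})

setMethod("show", "QuantizedVolume", function(object) {
  cat(sprintf("QuantizedVolume: Ng = %d levels (bin width %.4g, anchor %.4g)\n",
              object@nLevels, object@binWidth, object@intensityMin))
})

setMethod("show", "WaveletBank", function(object) {
  d <- dim(object@components[[1]])
  cat(sprintf("WaveletBank (%s): 9 components on a %d x %d x %d grid\n",
              object@basis, d[1], d[2], d[3]))
})

setMethod("show", "ResponseModel", function(object) {
  cat(sprintf("ResponseModel <%s> on %d features (seed %d)\n",
              object@algorithm, length(object@featureIds), object@seed))
})
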