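#' First-order (histogram) features of a component image
#'
#' Ten statistics of the in-mask intensities: energy (sum of squared
#' intensities), entropy and uniformity of the fixed-bin-width
#' probability vector (bits; bin width as used for texture
#' quantization), mean, population variance, skewness, Pearson
#' (non-excess) kurtosis, minimum, maximum and range. For a
#' zero-variance region skewness and kurtosis are undefined and
#' returned as `NA` (flagged missing, not propagated).
#'
#' @param img a [CTVolume-class] component image.
#' @param mask a [VOIMask-class] on the same grid.
#' @param bin_width bin width for the entropy/uniformity histogram
#'   (default 25).
#' @return named numeric(10): Energy, Entropy, Uniformity, Mean,
#'   Variance, Skewness, Kurtosis, Minimum, Maximum, Range.
#' @export
histogramFeatures <- function(img, mask, bin_width = 25) {
  x <- voxelData(img)[voxelData(mask) == 1L]
  if (length(x) < 2) stop("need at least 2 in-mask voxels")
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  q <- quantizeVolume(img, mask, bin_width)
  lv <- voxelData(q)[!is.na(voxelData(q))]
  p <- tabulate(lv, nbins = nLevels(q)) / length(lv)
  p <- p[p > 0]
  if (v > 0) {
    skew <- mean((x - mu)^3) / v^1.5
    kurt <- mean((x - mu)^4) / v^2
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  c(Energy = sum(x^2),
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2),
    Mean = mu,
    Variance = v,
    Skewness = skew,
    Kurtosis = kurt,
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x))
}
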