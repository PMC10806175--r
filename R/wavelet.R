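# Analysis filter pairs (convolution order). The high-pass filter is the
# quadrature mirror of the low-pass: h[k] = (-1)^(k-1) * g[L - k + 1].
.WAVELET_FILTERS <- list(
  haar = list(lo = c(0.7071067811865476, 0.7071067811865476)),
  coif1 = list(lo = c(-0.015655728135791993, -0.07273261951252645,
                      0.3848648468648578, 0.8525720202116004,
                      0.3378976624574818, -0.07273261951252645)))

.qmfHigh <- function(lo) {
  L <- length(lo)
  (-1)^(seq_len(L) - 1) * rev(lo)
}

#' Single-level undecimated 3D wavelet decomposition
#'
#' Applies the separable low/high analysis pair along each axis without
#' downsampling (stationary transform, symmetric boundary padding), so
#' every subband stays on the input grid and in register with the VOI
#' mask. The 2^3 filter combinations give the 8 subbands; with the
#' original image they form the 9 component images from which histogram
#' and texture features are extracted. Names give the filter per axis in
#' (x, y, z) order: `HLL` is high-pass along x only.
#'
#' @param vol a [CTVolume-class].
#' @param basis "coif1" (default) or "haar".
#' @return a [WaveletBank-class] with components ROI, LLL, ..., HHH.
#' @export
waveletDecompose <- function(vol, basis = c("coif1", "haar")) {
  basis <- match.arg(basis)
  lo <- .WAVELET_FILTERS[[basis]]$lo
  hi <- .qmfHigh(lo)
  a <- voxelData(vol)
  if (any(dim(a) < length(lo)))
    stop(sprintf("volume %s is smaller than the %s filter support (%d taps)",
                 paste(dim(a), collapse = "x"), basis, length(lo)))
  lx <- .filterAxis(a, lo, 1); hx <- .filterAxis(a, hi, 1)
  comps <- list(ROI = a)
  for (fx in c("L", "H")) {
    ax <- if (fx == "L") lx else hx
    ly <- .filterAxis(ax, lo, 2); hy <- .filterAxis(ax, hi, 2)
    for (fy in c("L", "H")) {
      ay <- if (fy == "L") ly else hy
      for (fz in c("L", "H")) {
        f <- if (fz == "L") lo else hi
        comps[[paste0(fx, fy, fz)]] <- .filterAxis(ay, f, 3)
      }
    }
  }
  comps <- comps[.WAVELET_COMPONENTS]
  new("WaveletBank", components = comps, basis = basis,
      spacing = voxelSpacing(vol), origin = voxelOrigin(vol))
}

#' Dump the component images of a bank as NIfTI files
#'
#' Debug aid for visual inspection of the subbands.
#'
#' @param bank a [WaveletBank-class].
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return the written paths, invisibly.
#' @export
writeBankNifti <- function(bank, dir, prefix = "component") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(componentNames(bank), function(nm) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    writeCaseNifti(CTVolume(componentImage(bank, nm), voxelSpacing(bank)), p)
    p
  }, character(1))
  invisible(paths)
}
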