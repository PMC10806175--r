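#' Crop a volume and mask to the VOI bounding box plus padding
#'
#' Bounds memory for the wavelet/resampling stages without touching
#' in-mask statistics.
#'
#' @param vol a [CTVolume-class].
#' @param mask a [VOIMask-class] on the same grid.
#' @param pad margin in voxels around the mask bounding box (default 8),
#'   clamped to the grid.
#' @return list with cropped `volume` and `mask` (origin updated so world
#'   coordinates are preserved).
#' @export
cropToMask <- function(vol, mask, pad = 8L) {
  m <- voxelData(mask)
  d <- dim(m)
  idx <- which(m == 1L, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  v <- voxelData(vol)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mm <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sp <- voxelSpacing(vol)
  org <- voxelOrigin(vol) + (lo - 1) * sp
  list(volume = CTVolume(v, sp, org), mask = VOIMask(mm, sp, org))
}

#' Resample a volume and mask to isotropic spacing
#'
#' The image is trilinearly interpolated and the mask nearest-neighbor
#' resampled onto an isotropic grid covering the input field of view
#' (hence the whole VOI bounding box). Used with the default 2-mm
#' target before feature extraction.
#'
#' @param vol a [CTVolume-class].
#' @param mask a [VOIMask-class] on the same grid.
#' @param target isotropic spacing (mm), > 0; default 2.
#' @return list with resampled `volume` and `mask`.
#' @export
resampleIsotropic <- function(vol, mask, target = 2.0) {
  stopifnot(target > 0)
  plan <- .resamplePlan(vol, target)
  out_v <- array(.applyTrilinear(voxelData(vol), plan$plan), dim = plan$dims)
  out_m <- array(as.integer(voxelData(mask)[plan$plan$nn] > 0),
                 dim = plan$dims)
  if (sum(out_m) == 0)
    stop("VOI collapsed to zero voxels at ", target, " mm resampling")
  sp <- rep(target, 3)
  list(volume = CTVolume(out_v, sp, plan$origin),
       mask = VOIMask(out_m, sp, plan$origin))
}

# Shared resampling geometry + interpolation plan, reusable across the
# 9 wavelet components of one case (all live on the same grid).
.resamplePlan <- function(vol, target) {
  d <- dim(voxelData(vol))
  sp <- voxelSpacing(vol)
  org <- voxelOrigin(vol)
  extent <- (d - 1) * sp
  nd <- pmax(1L, as.integer(floor(extent / target)) + 1L)
  ax <- lapply(1:3, function(a) org[a] + (seq_len(nd[a]) - 1) * target)
  pts <- cbind(rep(ax[[1]], times = nd[2] * nd[3]),
               rep(rep(ax[[2]], each = nd[1]), times = nd[3]),
               rep(ax[[3]], each = nd[1] * nd[2]))
  list(plan = .trilinearPlan(d, sp, org, pts), dims = nd, origin = org)
}

#' Requantize intensities with a fixed bin width
#'
#' In-mask intensities are mapped to gray levels
#' `floor((I - min_in_mask) / bin_width) + 1`, so levels start at 1 and
#' `Ng = floor((max - min) / bin_width) + 1`. The anchor is the in-mask
#' minimum of the image being quantized; wavelet subbands (not in HU)
#' reuse the same fixed width on their own scale. Adding a constant to
#' all intensities leaves the levels unchanged.
#'
#' @param vol a [CTVolume-class] (or any component image on the grid).
#' @param mask a [VOIMask-class] on the same grid.
#' @param bin_width bin width, > 0; default 25 (HU).
#' @return a [QuantizedVolume-class].
#' @export
quantizeVolume <- function(vol, mask, bin_width = 25) {
  stopifnot(bin_width > 0)
  v <- voxelData(vol)
  m <- voxelData(mask) == 1L
  lo <- min(v[m])
  lev <- array(NA_integer_, dim = dim(v))
  lev[m] <- as.integer(floor((v[m] - lo) / bin_width)) + 1L
  ng <- as.integer(floor((max(v[m]) - lo) / bin_width)) + 1L
  new("QuantizedVolume", levels = lev, binWidth = bin_width,
      nLevels = ng, intensityMin = lo)
}
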