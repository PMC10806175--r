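#' Construct a CTVolume
#'
#' @param voxels 3D numeric array (HU).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) world origin in mm.
#' @return a [CTVolume-class].
#' @export
CTVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a VOIMask
#'
#' Values > 0 are binarized to 1 (labelled masks are accepted).
#'
#' @param voxels 3D array; any positive value marks foreground.
#' @param spacing numeric(3) mm.
#' @param origin numeric(3) mm.
#' @return a [VOIMask-class].
#' @export
VOIMask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- array(as.integer(voxels > 0), dim = dim(voxels))
  new("VOIMask", voxels = v, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

# Convolve a 3D array along one axis with a short FIR filter, symmetric
# (half-sample mirror) padding, "same"-length output. Alignment uses a
# centered window so a one-voxel input shift produces a one-voxel output
# shift away from the boundaries.
.filterAxis <- function(a, f, axis) {
  d <- dim(a)
  n <- d[axis]
  L <- length(f)
  if (n < L) stop("volume smaller than filter support along axis ", axis)
  pl <- (L - 1L) %/% 2L
  pr <- L - 1L - pl
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(a, perm)
  dim(x) <- c(n, prod(d[-axis]))
  idx <- c(if (pl > 0) rev(seq_len(pl)) else integer(),
           seq_len(n),
           if (pr > 0) n - seq_len(pr) + 1L else integer())
  xe <- x[idx, , drop = FALSE]
  y <- matrix(0, n, ncol(x))
  for (k in seq_len(L))
    y <- y + f[k] * xe[(seq_len(n)) + k - 1L, , drop = FALSE]
  dim(y) <- d[perm]
  aperm(y, order(perm))
}

# Separable Gaussian smoothing; sigma per axis in voxels (0 = identity).
.gaussianSmooth <- function(a, sigma) {
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    if (dim(a)[ax] < length(k)) {
      # truncate kernel for short axes rather than failing
      r <- max(1L, (dim(a)[ax] - 1L) %/% 2L)
      k <- exp(-0.5 * ((-r:r) / s)^2)
      k <- k / sum(k)
    }
    a <- .filterAxis(a, k, ax)
  }
  a
}

# Precompute trilinear interpolation weights from an input grid (dims d,
# spacing sp, origin o) onto query world coordinates (3-column matrix).
# Returns index/weight pairs usable on any array sharing the input grid.
.trilinearPlan <- function(d, sp, o, pts) {
  cx <- (pts[, 1] - o[1]) / sp[1]
  cy <- (pts[, 2] - o[2]) / sp[2]
  cz <- (pts[, 3] - o[3]) / sp[3]
  cx <- pmin(pmax(cx, 0), d[1] - 1)
  cy <- pmin(pmax(cy, 0), d[2] - 1)
  cz <- pmin(pmax(cz, 0), d[3] - 1)
  x0 <- pmin(floor(cx), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(cy), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(cz), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1) x0 <- rep(0, length(cx))
  if (d[2] == 1) y0 <- rep(0, length(cy))
  if (d[3] == 1) z0 <- rep(0, length(cz))
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  idx <- matrix(0L, length(cx), 8)
  w <- matrix(0, length(cx), 8)
  corner <- 1L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    xi <- pmin(x0 + dx, d[1] - 1)
    yi <- pmin(y0 + dy, d[2] - 1)
    zi <- pmin(z0 + dz, d[3] - 1)
    idx[, corner] <- 1L + xi + d[1] * (yi + d[2] * zi)
    w[, corner] <- (if (dx) fx else 1 - fx) *
                   (if (dy) fy else 1 - fy) *
                   (if (dz) fz else 1 - fz)
    corner <- corner + 1L
  }
  list(idx = idx, w = w,
       nn = 1L + round(cx) + d[1] * (round(cy) + d[2] * round(cz)))
}

.applyTrilinear <- function(a, plan) {
  v <- rep(0, nrow(plan$idx))
  for (corner in 1:8)
    v <- v + plan$w[, corner] * a[plan$idx[, corner]]
  v
}

# Minimal union-find with path halving, for zone labeling.
.unionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  list(find = find, union = union, roots = function() {
    vapply(seq_len(n), find, integer(1))
  })
}

# The 13 unique 3D offsets (one per opposite pair of the 26 neighbors).
.DIRECTIONS_13 <- {
  ds <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ds <- ds[!(ds$dx == 0 & ds$dy == 0 & ds$dz == 0), ]
  keep <- ds$dz > 0 | (ds$dz == 0 & ds$dy > 0) |
    (ds$dz == 0 & ds$dy == 0 & ds$dx > 0)
  as.matrix(ds[keep, ])
}

# Deterministic sub-seed derivation (kept below 2^31).
.subSeed <- function(seed, k) {
  (as.numeric(seed) * 1103L + k * 12347) %% 2147483629
}

.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}
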