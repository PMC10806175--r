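# Shift a 3D array by one voxel along an axis, filling with 0.
.shift1 <- function(a, axis, step) {
  d <- dim(a)
  out <- array(0L, d)
  n <- d[axis]
  if (n <= 1 && abs(step) >= n) return(out)
  src <- lapply(1:3, function(i) seq_len(d[i]))
  dst <- src
  if (step > 0) { src[[axis]] <- 1:(n - 1); dst[[axis]] <- 2:n }
  else { src[[axis]] <- 2:n; dst[[axis]] <- 1:(n - 1) }
  piece <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(piece)))
}

#' Shape and size features of a VOI
#'
#' Eight descriptors computed from the binary mask and voxel spacing
#' alone: volume (voxel count x voxel volume), surface area (sum of
#' exposed voxel faces), their ratio, sphericity
#' `pi^(1/3) (6V)^(2/3) / A`, compactness1 `V / (sqrt(pi) A^(3/2))`,
#' compactness2 `36 pi V^2 / A^3`, spherical disproportion
#' `A / (4 pi R^2)` with `R = (3V / 4pi)^(1/3)`, and the maximum 3D
#' diameter (largest pairwise distance between surface voxel centers,
#' mm). Sphericity is scale-invariant; a ball scores near 1 and
#' elongated shapes lower.
#'
#' @param mask a [VOIMask-class].
#' @return named numeric(8).
#' @export
shapeFeatures <- function(mask) {
  m <- voxelData(mask)
  sp <- voxelSpacing(mask)
  nvox <- sum(m)
  if (nvox == 0) stop("empty mask")
  V <- nvox * prod(sp)

  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  A <- 0
  exposed <- array(FALSE, dim(m))
  for (ax in 1:3) for (st in c(-1L, 1L)) {
    nb <- .shift1(m, ax, st)
    faces <- m == 1L & nb == 0L
    A <- A + sum(faces) * face_area[ax]
    exposed <- exposed | faces
  }

  surf_idx <- which(exposed, arr.ind = TRUE)
  pts <- sweep(surf_idx - 1, 2, sp, `*`)
  max_diam <- if (nrow(pts) == 1) 0 else {
    sq <- rowSums(pts^2)
    mx <- 0
    chunk <- 1024L
    for (s in seq(1, nrow(pts), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(pts))
      d2 <- outer(sq[s:e], sq, `+`) - 2 * pts[s:e, , drop = FALSE] %*% t(pts)
      mx <- max(mx, max(d2))
    }
    sqrt(max(mx, 0))
  }

  R <- (3 * V / (4 * pi))^(1 / 3)
  c(volume = V,
    surface_area = A,
    surface_to_volume_ratio = A / V,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    compactness1 = V / (sqrt(pi) * A^(3 / 2)),
    compactness2 = 36 * pi * V^2 / A^3,
    spherical_disproportion = A / (4 * pi * R^2),
    max_3d_diameter = max_diam)
}
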