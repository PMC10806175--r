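# Gray-level texture matrices on the quantized, masked volume.
# GLCM and GLRLM are built per direction over the 13 unique 3D offsets
# and their features averaged across directions; GLSZM is a single
# matrix over 26-connected zones.

#' Build gray-level co-occurrence matrices
#'
#' For each of the 13 unique 3D direction vectors, counts in-mask voxel
#' pairs at the given offset (both endpoints inside the mask),
#' symmetrizes and normalizes. Directions with no valid pair are
#' dropped.
#'
#' @param q a [QuantizedVolume-class].
#' @param distance offset magnitude in voxels (default 1).
#' @return object of class `TextureMatrix` (kind "GLCM") holding one
#'   normalized symmetric `Ng x Ng` matrix per direction.
#' @export
buildGLCM <- function(q, distance = 1L) {
  lev <- voxelData(q)
  ng <- nLevels(q)
  d <- dim(lev)
  mats <- list()
  for (r in seq_len(nrow(.DIRECTIONS_13))) {
    off <- .DIRECTIONS_13[r, ] * distance
    rng <- lapply(1:3, function(a) {
      lo <- max(1L, 1L - off[a]); hi <- min(d[a], d[a] - off[a])
      if (lo > hi) integer() else lo:hi
    })
    if (any(!lengths(rng))) next
    a <- lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    b <- lev[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3],
             drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    counts <- tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng)
    P <- matrix(counts, ng, ng, byrow = TRUE)
    P <- P + t(P)
    mats[[paste(off, collapse = ",")]] <- P / sum(P)
  }
  if (!length(mats)) stop("no direction yields a co-occurrence pair")
  structure(list(kind = "GLCM", matrices = mats, nLevels = ng),
            class = "TextureMatrix")
}

#' Haralick-family features from co-occurrence matrices
#'
#' Twenty-two features with the standard definitions (contrast
#' `sum p(i,j) (i-j)^2`, homogeneity2 `sum p / (1 + (i-j)^2)`,
#' correlation `(sum ij p - mu_i mu_j) / (sigma_i sigma_j)`, ...),
#' computed per direction and averaged. On a single-gray-level region
#' the marginal sd is zero, so correlation, IMC1 and IMC2 are `NA`.
#'
#' @param tm a `TextureMatrix` from [buildGLCM()].
#' @return named numeric(22), ids prefixed with `G`.
#' @export
glcmFeatures <- function(tm) {
  stopifnot(tm$kind == "GLCM")
  per_dir <- lapply(tm$matrices, .glcmOne, ng = tm$nLevels)
  .averageDirections(per_dir)
}

.glcmOne <- function(P, ng) {
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(seq_len(ng) * px)
  mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  dif <- abs(i - j)
  # marginal distributions of |i-j| (k = 0..Ng-1) and i+j (k = 2..2Ng);
  # every k occurs in the full grid, so rowsum is index-aligned
  pd <- as.numeric(rowsum(as.vector(P), as.vector(dif)))
  ps <- as.numeric(rowsum(as.vector(P), as.vector(i + j)))
  ent0 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HXY <- ent0(P)
  pxy <- outer(px, py)
  nz <- P > 0 & pxy > 0
  HXY1 <- -sum(P[nz] * log2(pxy[nz]))
  HXY2 <- ent0(pxy)
  HX <- ent0(px)
  HY <- ent0(py)
  SA <- sum((2:(2 * ng)) * ps)
  corr <- if (sd_x > 0 && sd_y > 0)
    (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y) else NA_real_
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else NA_real_
  imc2 <- if (is.na(corr)) NA_real_ else
    sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  c(GAutocorrelation = sum(i * j * P),
    GClusterProminence = sum((i + j - mu_x - mu_y)^4 * P),
    GClusterShade = sum((i + j - mu_x - mu_y)^3 * P),
    GClusterTendency = sum((i + j - mu_x - mu_y)^2 * P),
    GContrast = sum((i - j)^2 * P),
    GCorrelation = corr,
    GDifferenceEntropy = ent0(pd),
    GDissimilarity = sum(dif * P),
    GEnergy = sum(P^2),
    GEntropy = HXY,
    GHomogeneity1 = sum(P / (1 + dif)),
    GHomogeneity2 = sum(P / (1 + (i - j)^2)),
    GIMC1 = imc1,
    GIMC2 = imc2,
    GIDMN = sum(P / (1 + (i - j)^2 / ng^2)),
    GIDN = sum(P / (1 + dif / ng)),
    GInverseVariance = sum(P[dif > 0] / dif[dif > 0]^2),
    GMaxProbability = max(P),
    GSumAverage = SA,
    GSumEntropy = ent0(ps),
    GSumVariance = sum(((2:(2 * ng)) - SA)^2 * ps),
    GVariance = sum((i - mu_x)^2 * P))
}

.averageDirections <- function(per_dir) {
  m <- do.call(rbind, per_dir)
  colMeans(m)  # NA in any direction keeps the feature flagged missing
}

#' Build gray-level run-length matrices
#'
#' Runs of consecutive equal gray levels along each of the 13 unique
#' directions, restricted to in-mask voxels; one `Ng x maxRunLength`
#' count matrix per direction.
#'
#' @param q a [QuantizedVolume-class].
#' @return `TextureMatrix` (kind "GLRLM") with raw count matrices and
#'   the in-mask voxel count.
#' @export
buildGLRLM <- function(q) {
  lev <- voxelData(q)
  ng <- nLevels(q)
  d <- dim(lev)
  np <- sum(!is.na(lev))
  step_of <- function(off) off[1] + d[1] * off[2] + d[1] * d[2] * off[3]
  mats <- list()
  for (r in seq_len(nrow(.DIRECTIONS_13))) {
    off <- .DIRECTIONS_13[r, ]
    # same_next[v]: v + off is inside grid & mask with the same level
    same_next <- array(FALSE, d)
    rng <- lapply(1:3, function(a) {
      lo <- max(1L, 1L - off[a]); hi <- min(d[a], d[a] - off[a])
      if (lo > hi) integer() else lo:hi
    })
    a <- lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    b <- lev[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3],
             drop = FALSE]
    same_next[rng[[1]], rng[[2]], rng[[3]]] <-
      !is.na(a) & !is.na(b) & a == b
    # run starts: in-mask voxels not continued from v - off
    same_prev <- array(FALSE, d)
    same_prev[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3]] <-
      same_next[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    starts <- which(!is.na(lev) & !same_prev)
    len <- rep(1L, length(starts))
    pos <- starts
    active <- seq_along(starts)
    step <- step_of(off)
    while (length(active)) {
      cont <- same_next[pos[active]]
      active <- active[cont]
      pos[active] <- pos[active] + step
      len[active] <- len[active] + 1L
    }
    maxlen <- max(len)
    counts <- tabulate((lev[starts] - 1L) * maxlen + len,
                       nbins = ng * maxlen)
    mats[[paste(off, collapse = ",")]] <-
      matrix(counts, ng, maxlen, byrow = TRUE)
  }
  structure(list(kind = "GLRLM", matrices = mats, nLevels = ng,
                 nVoxels = np), class = "TextureMatrix")
}

#' Run-length features
#'
#' Eleven features averaged over the 13 directions: SRE, LRE, GLN, RLN,
#' RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE. `RP` is the run count
#' divided by the in-mask voxel count.
#'
#' @param tm a `TextureMatrix` from [buildGLRLM()].
#' @return named numeric(11).
#' @export
glrlmFeatures <- function(tm) {
  stopifnot(tm$kind == "GLRLM")
  per_dir <- lapply(tm$matrices, function(M) {
    nr <- sum(M)
    i2 <- matrix(seq_len(nrow(M))^2, nrow(M), ncol(M))
    l2 <- matrix(rep(seq_len(ncol(M))^2, each = nrow(M)), nrow(M))
    c(SRE = sum(M / l2) / nr,
      LRE = sum(M * l2) / nr,
      GLN = sum(rowSums(M)^2) / nr,
      RLN = sum(colSums(M)^2) / nr,
      RP = nr / tm$nVoxels,
      LGRE = sum(M / i2) / nr,
      HGRE = sum(M * i2) / nr,
      SRLGE = sum(M / (i2 * l2)) / nr,
      SRHGE = sum(M * i2 / l2) / nr,
      LRLGE = sum(M * l2 / i2) / nr,
      LRHGE = sum(M * i2 * l2) / nr)
  })
  .averageDirections(per_dir)
}

#' Build the gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level within the
#' mask; a single `Ng x maxZoneSize` count matrix (no directions).
#'
#' @param q a [QuantizedVolume-class].
#' @return `TextureMatrix` (kind "GLSZM").
#' @export
buildGLSZM <- function(q) {
  lev <- voxelData(q)
  ng <- nLevels(q)
  d <- dim(lev)
  vox <- which(!is.na(lev))
  np <- length(vox)
  id_of <- rep(NA_integer_, prod(d))
  id_of[vox] <- seq_len(np)
  uf <- .unionFind(np)
  for (r in seq_len(nrow(.DIRECTIONS_13))) {
    off <- .DIRECTIONS_13[r, ]
    rng <- lapply(1:3, function(a) {
      lo <- max(1L, 1L - off[a]); hi <- min(d[a], d[a] - off[a])
      if (lo > hi) integer() else lo:hi
    })
    a <- lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    b <- lev[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3],
             drop = FALSE]
    lin <- array(seq_len(prod(d)), d)
    la <- lin[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    lb <- lin[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3],
              drop = FALSE]
    ok <- which(!is.na(a) & !is.na(b) & a == b)
    for (k in ok) uf$union(id_of[la[k]], id_of[lb[k]])
  }
  roots <- uf$roots()
  zsize <- as.integer(table(roots))
  # level per zone: the level of any member of each root's group
  zlev <- vapply(split(lev[vox], roots), `[`, numeric(1), 1)
  maxs <- max(zsize)
  counts <- tabulate((as.integer(zlev) - 1L) * maxs + zsize,
                     nbins = ng * maxs)
  M <- matrix(counts, ng, maxs, byrow = TRUE)
  structure(list(kind = "GLSZM", matrices = list(M), nLevels = ng,
                 nVoxels = np), class = "TextureMatrix")
}

#' Size-zone features
#'
#' Nine features: SZE, LZE, ZGLN (zone gray-level non-uniformity), ZSN,
#' ZP, LGZE, HGZE, SZLGE, SZHGE. `ZP` is zones / in-mask voxels and
#' `LZE = sum p(i,s) s^2` over normalized-by-zone-count entries.
#'
#' @param tm a `TextureMatrix` from [buildGLSZM()].
#' @return named numeric(9).
#' @export
glszmFeatures <- function(tm) {
  stopifnot(tm$kind == "GLSZM")
  M <- tm$matrices[[1]]
  nz <- sum(M)
  i2 <- matrix(seq_len(nrow(M))^2, nrow(M), ncol(M))
  s2 <- matrix(rep(seq_len(ncol(M))^2, each = nrow(M)), nrow(M))
  c(SZE = sum(M / s2) / nz,
    LZE = sum(M * s2) / nz,
    ZGLN = sum(rowSums(M)^2) / nz,
    ZSN = sum(colSums(M)^2) / nz,
    ZP = nz / tm$nVoxels,
    LGZE = sum(M / i2) / nz,
    HGZE = sum(M * i2) / nz,
    SZLGE = sum(M / (i2 * s2)) / nz,
    SZHGE = sum(M * i2 / s2) / nz)
}
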