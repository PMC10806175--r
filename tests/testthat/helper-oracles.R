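# Independent brute-force oracles used to cross-check the vectorized
# texture-matrix builders, the AUC, and the Cox fit. Deliberately naive
# (triple loops, recursion, grid search) so they share no code with the
# implementation.

# All voxel pairs at offset `off` with both endpoints in mask:
# returns an Ng x Ng symmetrized count matrix.
oracleGLCM <- function(lev, off, ng) {
  d <- dim(lev)
  M <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
        z2 < 1 || z2 > d[3]) next
    b <- lev[x2, y2, z2]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
  }
  M + t(M)
}

# All runs along offset `off`: Ng x maxlen count matrix.
oracleGLRLM <- function(lev, off, ng) {
  d <- dim(lev)
  inside <- function(p) all(p >= 1) && all(p <= d)
  val <- function(p) lev[p[1], p[2], p[3]]
  runs <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    p <- c(x, y, z)
    v <- val(p)
    if (is.na(v)) next
    prev <- p - off
    if (inside(prev) && !is.na(val(prev)) && val(prev) == v) next
    len <- 1
    nxt <- p + off
    while (inside(nxt) && !is.na(val(nxt)) && val(nxt) == v) {
      len <- len + 1
      nxt <- nxt + off
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  runs <- do.call(rbind, runs)
  maxlen <- max(runs[, 2])
  M <- matrix(0, ng, maxlen)
  for (r in seq_len(nrow(runs)))
    M[runs[r, 1], runs[r, 2]] <- M[runs[r, 1], runs[r, 2]] + 1
  M
}

# 26-connected zones of equal level via breadth-first flood fill:
# Ng x maxsize count matrix.
oracleGLSZM <- function(lev, ng) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs == 0) < 3, ]
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || is.na(lev[x, y, z])) next
    v <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (seen[q[1], q[2], q[3]]) next
        w <- lev[q[1], q[2], q[3]]
        if (is.na(w) || w != v) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(v, size)
  }
  zones <- do.call(rbind, zones)
  M <- matrix(0, ng, max(zones[, 2]))
  for (r in seq_len(nrow(zones)))
    M[zones[r, 1], zones[r, 2]] <- M[zones[r, 1], zones[r, 2]] + 1
  M
}

# AUC by exhaustive pair enumeration (ties count 1/2).
oracleAUC <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Hand product-limit estimator over the distinct event times.
oracleKM <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  list(time = ts, surv = out)
}

# Partial log-likelihood for a single covariate (Breslow form; exact
# for data without tied event times) maximized on a coarse grid.
oracleCoxGrid <- function(time, event, x, grid = seq(-5, 5, by = 1e-3)) {
  ll <- vapply(grid, function(b) {
    eta <- b * x
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + eta[i] - log(sum(exp(eta[risk])))
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

# A quantized toy volume straight from a levels array (NA = outside
# the mask), bypassing quantizeVolume so matrix-builder tests do not
# depend on it.
makeQuantized <- function(lev_array) {
  storage.mode(lev_array) <- "integer"
  methods::new("QuantizedVolume", levels = lev_array, binWidth = 1,
               nLevels = max(lev_array, na.rm = TRUE),
               intensityMin = 0)
}

# Random Ng <= 4 quantized volume on a 6^3 grid with a random mask.
randomQuantized <- function(seed, p_mask = 0.8, ng = 4) {
  set.seed(seed)
  lev <- array(sample.int(ng, 6^3, replace = TRUE), c(6, 6, 6))
  lev[runif(6^3) > p_mask] <- NA
  if (all(is.na(lev))) lev[1, 1, 1] <- 1
  lev[1, 1, 1] <- 1  # guarantee non-empty and level 1 present
  storage.mode(lev) <- "integer"
  lev
}

# Tiny two-class feature cohort with a tunable class effect on the
# first `n_informative` features.
toyFeatureMatrix <- function(seed, n_features = 30, n_cases = 27,
                             n_pos = 6, effect = 0, n_informative = 5) {
  set.seed(seed)
  labels <- c(rep(1, n_pos), rep(0, n_cases - n_pos))
  m <- matrix(rnorm(n_features * n_cases), n_features, n_cases,
              dimnames = list(sprintf("f%03d", seq_len(n_features)),
                              sprintf("case_%03d", seq_len(n_cases))))
  m[seq_len(n_informative), labels == 1] <-
    m[seq_len(n_informative), labels == 1] + effect
  list(m = m, labels = labels)
}
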