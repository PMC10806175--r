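#' Texture parameters for one response class of synthetic tumors
#'
#' Describes the correlated Gaussian random field filling the phantom
#' tumor: the in-mask HU mean and standard deviation, the correlation
#' length (the Gaussian blur scale of the field, in mm; 0 gives white
#' noise), and the ellipsoid geometry.
#'
#' @param mean_hu in-mask mean intensity (HU).
#' @param sd_hu in-mask standard deviation (HU), >= 0.
#' @param correlation_length blur scale of the random field (mm), >= 0.
#' @param ellipsoid_radii numeric(3) semi-axes (mm), all > 0.
#' @param radius_jitter fraction by which each semi-axis is jittered
#'   uniformly per case (0 = fixed shape).
#' @return a validated list of class `ClassTextureParams`.
#' @export
classTextureParams <- function(mean_hu = 50, sd_hu = 30,
                               correlation_length = 2,
                               ellipsoid_radii = c(11, 10, 8),
                               radius_jitter = 0.1) {
  stopifnot(sd_hu >= 0, correlation_length >= 0,
            length(ellipsoid_radii) == 3, all(ellipsoid_radii > 0),
            radius_jitter >= 0, radius_jitter < 1)
  structure(list(mean_hu = mean_hu, sd_hu = sd_hu,
                 correlation_length = correlation_length,
                 ellipsoid_radii = as.numeric(ellipsoid_radii),
                 radius_jitter = radius_jitter),
            class = "ClassTextureParams")
}

#' Survival-simulation parameters
#'
#' Event times are exponential; responders have their hazard multiplied
#' by `responder_hazard_ratio` (< 1 means responders progress later).
#' Overall survival is progression-free survival plus an independent
#' exponential gap, so OS >= PFS by construction. Administrative
#' censoring is applied at `censor_horizon`.
#'
#' @param baseline_median_pfs non-responder median PFS (months).
#' @param baseline_median_os non-responder median OS (months); must
#'   exceed `baseline_median_pfs`.
#' @param responder_hazard_ratio hazard multiplier for responders, > 0.
#' @param censor_horizon administrative censoring time (months), > 0.
#' @return a validated list of class `SurvivalSimParams`.
#' @export
survivalSimParams <- function(baseline_median_pfs = 6,
                              baseline_median_os = 13,
                              responder_hazard_ratio = 0.12,
                              censor_horizon = 90) {
  stopifnot(baseline_median_pfs > 0, baseline_median_os > baseline_median_pfs,
            responder_hazard_ratio > 0)
  if (censor_horizon <= 0)
    stop("censor_horizon must be > 0 (a zero horizon censors everything)")
  structure(list(baseline_median_pfs = baseline_median_pfs,
                 baseline_median_os = baseline_median_os,
                 responder_hazard_ratio = responder_hazard_ratio,
                 censor_horizon = censor_horizon),
            class = "SurvivalSimParams")
}

#' Configuration of a synthetic CRT cohort
#'
#' Defaults mirror the clinical design the pipeline targets: 27 training
#' and 17 validation cases with 6 responders in each cohort (22.2% and
#' 35.3% prevalence), CT-like anisotropic voxels, and responder tumors
#' whose random-field texture is smoother and more variable than
#' non-responder tumors.
#'
#' @param n_train,n_validation cohort sizes.
#' @param prevalence_train,prevalence_validation responder fractions in
#'   (0, 1); responder counts are `round(prevalence * n)`.
#' @param responder_params,nonresponder_params [classTextureParams()]
#'   per class.
#' @param hazard [survivalSimParams()].
#' @param grid_shape integer(3) phantom grid.
#' @param spacing numeric(3) voxel spacing (mm).
#' @param seed integer master seed.
#' @return a validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(n_train = 27L, n_validation = 17L,
                         prevalence_train = 6 / 27,
                         prevalence_validation = 6 / 17,
                         responder_params = classTextureParams(
                           mean_hu = 35, sd_hu = 55,
                           correlation_length = 4,
                           ellipsoid_radii = c(11, 10, 8)),
                         nonresponder_params = classTextureParams(
                           mean_hu = 60, sd_hu = 20,
                           correlation_length = 1,
                           ellipsoid_radii = c(12, 10, 8)),
                         hazard = survivalSimParams(),
                         grid_shape = c(48L, 48L, 24L),
                         spacing = c(0.976, 0.976, 2.5),
                         seed = 1L) {
  stopifnot(n_train >= 0, n_validation >= 0, n_train + n_validation > 0)
  for (p in c(prevalence_train, prevalence_validation))
    if (p <= 0 || p >= 1) stop("prevalence must be in (0, 1)")
  stopifnot(inherits(responder_params, "ClassTextureParams"),
            inherits(nonresponder_params, "ClassTextureParams"),
            inherits(hazard, "SurvivalSimParams"),
            length(grid_shape) == 3, length(spacing) == 3,
            all(spacing > 0))
  structure(list(n_train = as.integer(n_train),
                 n_validation = as.integer(n_validation),
                 prevalence_train = prevalence_train,
                 prevalence_validation = prevalence_validation,
                 responder_params = responder_params,
                 nonresponder_params = nonresponder_params,
                 hazard = hazard,
                 grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Generate one CT-like tumor phantom
#'
#' Builds a jittered-ellipsoid VOI centered in the grid and fills it with
#' a stationary correlated Gaussian field: white noise is Gaussian-blurred
#' at the class correlation length, rescaled to the target in-mask sd,
#' and shifted to the class mean. The background is air-like (-700 HU)
#' with mild soft-tissue-scale noise so tumor and background are
#' unambiguous.
#'
#' @param params a [classTextureParams()].
#' @param grid_shape integer(3) grid size in voxels.
#' @param spacing numeric(3) mm.
#' @param rng_seed integer seed; the phantom is a pure function of
#'   (params, grid, seed).
#' @return list with elements `volume` ([CTVolume-class]) and `mask`
#'   ([VOIMask-class]).
#' @export
generatePhantom <- function(params, grid_shape, spacing, rng_seed) {
  stopifnot(inherits(params, "ClassTextureParams"))
  d <- as.integer(grid_shape)
  sp <- as.numeric(spacing)
  set.seed(as.integer(rng_seed %% 2147483629))
  jit <- 1 + params$radius_jitter * runif(3, -1, 1)
  radii <- params$ellipsoid_radii * jit
  half_extent <- (d - 1) / 2 * sp
  if (any(radii + 2 * sp > half_extent))
    stop(sprintf(
      "ellipsoid (radii %.1f x %.1f x %.1f mm) does not fit the %d x %d x %d grid with a 2-voxel margin",
      radii[1], radii[2], radii[3], d[1], d[2], d[3]))
  ctr <- (d - 1) / 2
  xs <- ((seq_len(d[1]) - 1) - ctr[1]) * sp[1] / radii[1]
  ys <- ((seq_len(d[2]) - 1) - ctr[2]) * sp[2] / radii[2]
  zs <- ((seq_len(d[3]) - 1) - ctr[3]) * sp[3] / radii[3]
  r2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  mask <- array(as.integer(r2 <= 1), dim = d)

  vox <- array(-700 + rnorm(prod(d), 0, 15), dim = d)
  inside <- mask == 1L
  if (params$sd_hu == 0) {
    vox[inside] <- params$mean_hu
  } else {
    field <- array(rnorm(prod(d)), dim = d)
    if (params$correlation_length > 0)
      field <- .gaussianSmooth(field, params$correlation_length / sp)
    s <- sd(field)
    field <- field / s * params$sd_hu
    vox[inside] <- params$mean_hu + field[inside]
  }
  list(volume = CTVolume(vox, sp), mask = VOIMask(mask, sp))
}

#' Simulate PFS and OS for one case
#'
#' @param responder logical response label.
#' @param hazard a [survivalSimParams()].
#' @param rng_seed integer seed.
#' @return data.frame with `pfs_months`, `pfs_event`, `os_months`,
#'   `os_event` (event = 1 observed, 0 administratively censored).
#' @export
simulateOutcomes <- function(responder, hazard, rng_seed) {
  stopifnot(inherits(hazard, "SurvivalSimParams"))
  set.seed(as.integer(rng_seed %% 2147483629))
  hr <- if (responder) hazard$responder_hazard_ratio else 1
  lambda_pfs <- log(2) / hazard$baseline_median_pfs * hr
  # gap hazard calibrated so the compound OS median is ~ baseline_median_os
  lambda_gap <- log(2) /
    (hazard$baseline_median_os - hazard$baseline_median_pfs) * hr
  pfs <- rexp(1, lambda_pfs)
  os <- pfs + rexp(1, lambda_gap)
  h <- hazard$censor_horizon
  data.frame(pfs_months = min(pfs, h), pfs_event = as.integer(pfs <= h),
             os_months = min(os, h), os_event = as.integer(os <= h))
}

.simulateCovariates <- function(responder, rng) {
  # class-dependent categorical covariates so multivariate Cox inputs
  # are non-degenerate: responders skew to lower T/N stage
  if (responder) {
    t_stage <- sample(1:4, 1, prob = c(0.25, 0.3, 0.3, 0.15))
    n_stage <- sample(0:4, 1, prob = c(0.35, 0.3, 0.2, 0.1, 0.05))
  } else {
    t_stage <- sample(1:4, 1, prob = c(0.05, 0.1, 0.4, 0.45))
    n_stage <- sample(0:4, 1, prob = c(0.1, 0.2, 0.3, 0.2, 0.2))
  }
  data.frame(
    age = round(runif(1, 47, 96)),
    sex = sample(c("M", "F"), 1, prob = c(0.85, 0.15)),
    t_stage = t_stage, n_stage = n_stage,
    scc = round(rlnorm(1, meanlog = 0.1, sdlog = 0.7), 2),
    location = sample(c("Ut", "Mt", "Lt"), 1, prob = c(0.2, 0.5, 0.3)))
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one NIfTI image and one NIfTI mask per case plus
#' `clinical.csv` and a JSON provenance file recording the full
#' configuration. Responder counts are exactly
#' `round(prevalence * n)` per cohort; case order and all randomness are
#' a pure function of `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @param out_dir output directory (created if missing).
#' @param force overwrite an existing non-empty directory.
#' @return invisibly, a list with `clinical` (data.frame), `image_paths`,
#'   `mask_paths`, and `config`.
#' @export
generateCohort <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "CohortConfig"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  mk_labels <- function(n, prev) {
    if (n == 0) return(integer())
    npos <- round(prev * n)
    c(rep(1L, npos), rep(0L, n - npos))
  }
  cohorts <- c(rep("training", config$n_train),
               rep("validation", config$n_validation))
  labels <- c(mk_labels(config$n_train, config$prevalence_train),
              mk_labels(config$n_validation, config$prevalence_validation))
  n <- length(labels)
  clin <- NULL
  image_paths <- mask_paths <- character(n)
  for (i in seq_len(n)) {
    case_id <- sprintf("case_%03d", i)
    responder <- labels[i] == 1L
    p <- if (responder) config$responder_params else config$nonresponder_params
    ph <- tryCatch(
      generatePhantom(p, config$grid_shape, config$spacing,
                      .subSeed(config$seed, i)),
      error = function(e) stop("case ", case_id, ": ", conditionMessage(e)))
    image_paths[i] <- file.path(out_dir, paste0(case_id, "_image.nii.gz"))
    mask_paths[i] <- file.path(out_dir, paste0(case_id, "_mask.nii.gz"))
    writeCaseNifti(ph$volume, image_paths[i])
    writeCaseNifti(ph$mask, mask_paths[i])
    surv <- simulateOutcomes(responder, config$hazard,
                             .subSeed(config$seed, 100000 + i))
    set.seed(as.integer(.subSeed(config$seed, 200000 + i)))
    cov <- .simulateCovariates(responder, NULL)
    clin <- rbind(clin, cbind(
      data.frame(case_id = case_id, cohort = cohorts[i],
                 response = labels[i]),
      surv[, c("pfs_months", "pfs_event", "os_months", "os_event")],
      cov))
  }
  clin <- clin[, c("case_id", "cohort", "response", "pfs_months",
                   "pfs_event", "os_months", "os_event", "t_stage",
                   "n_stage", "scc", "location", "age", "sex")]
  write.csv(clin, file.path(out_dir, "clinical.csv"), row.names = FALSE)
  prov <- list(config = unclass(config), n_cases = n,
               generated_by = "RadCRT::generateCohort")
  prov$config$responder_params <- unclass(prov$config$responder_params)
  prov$config$nonresponder_params <- unclass(prov$config$nonresponder_params)
  prov$config$hazard <- unclass(prov$config$hazard)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(clinical = clin, image_paths = image_paths,
                 mask_paths = mask_paths, config = config))
}
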