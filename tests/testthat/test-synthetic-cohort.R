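test_that("phantom field honors the requested moments and determinism", {
  sp <- c(1, 1, 1)
  gs <- c(40, 40, 40)

  # zero-variance field: every in-mask voxel equals the class mean
  p0 <- classTextureParams(mean_hu = 42, sd_hu = 0, correlation_length = 2,
                           ellipsoid_radii = c(10, 9, 8),
                           radius_jitter = 0)
  ph <- generatePhantom(p0, gs, sp, 7)
  vals <- voxelData(ph$volume)[voxelData(ph$mask) == 1L]
  expect_true(all(vals == 42))

  # same seed, same params -> bit-identical volume and mask
  ph2 <- generatePhantom(p0, gs, sp, 7)
  expect_identical(voxelData(ph$volume), voxelData(ph2$volume))
  expect_identical(voxelData(ph$mask), voxelData(ph2$mask))

  # white-noise field: in-mask sd within 5% of the target
  pw <- classTextureParams(mean_hu = 0, sd_hu = 30, correlation_length = 0,
                           ellipsoid_radii = c(15, 15, 15),
                           radius_jitter = 0)
  phw <- generatePhantom(pw, gs, sp, 11)
  vw <- voxelData(phw$volume)[voxelData(phw$mask) == 1L]
  expect_gt(length(vw), 1e4)
  expect_lt(abs(sd(vw) - 30) / 30, 0.05)
})

test_that("mask is an ellipsoid inside the grid; volume matches continuum", {
  p <- classTextureParams(ellipsoid_radii = c(8, 7, 6), radius_jitter = 0)
  ph <- generatePhantom(p, c(40, 40, 40), c(1, 1, 1), 3)
  m <- voxelData(ph$mask)
  # nothing on the boundary
  expect_equal(sum(m[c(1, 40), , ]) + sum(m[, c(1, 40), ]) +
                 sum(m[, , c(1, 40)]), 0)
  cont <- 4 / 3 * pi * 8 * 7 * 6
  expect_lt(abs(sum(m) - cont) / cont, 0.05)

  # oversized ellipsoid is rejected with a sizing error
  pbig <- classTextureParams(ellipsoid_radii = c(30, 30, 30))
  expect_error(generatePhantom(pbig, c(40, 40, 40), c(1, 1, 1), 3),
               "does not fit")
})

test_that("simulated event times recover the exponential median", {
  hz <- survivalSimParams(baseline_median_pfs = 8, baseline_median_os = 20,
                          responder_hazard_ratio = 1,
                          censor_horizon = 1e6)
  draws <- vapply(1:4000, function(i)
    simulateOutcomes(FALSE, hz, i)$pfs_months, numeric(1))
  expect_lt(abs(median(draws) - 8) / 8, 0.05)

  # OS >= PFS by construction
  recs <- lapply(1:50, function(i) simulateOutcomes(TRUE, hz, i))
  expect_true(all(vapply(recs, function(r)
    r$os_months >= r$pfs_months, logical(1))))

  # hazard ratio 1: responder and non-responder distributions identical
  dr <- vapply(1:2000, function(i)
    simulateOutcomes(TRUE, hz, 50000 + i)$pfs_months, numeric(1))
  dn <- vapply(1:2000, function(i)
    simulateOutcomes(FALSE, hz, 90000 + i)$pfs_months, numeric(1))
  expect_gt(suppressWarnings(ks.test(dr, dn)$p.value), 0.001)

  # degenerate censoring horizon rejected up front
  expect_error(survivalSimParams(censor_horizon = 0), "censor_horizon")
})

test_that("generateCohort writes the configured design deterministically", {
  cfg <- cohortConfig(seed = 5)
  d1 <- withr::local_tempdir()
  b1 <- generateCohort(cfg, d1, force = TRUE)
  expect_equal(nrow(b1$clinical), 44)
  expect_equal(sum(b1$clinical$response), 12)
  expect_equal(sum(b1$clinical$response[b1$clinical$cohort == "training"]), 6)
  expect_equal(sum(b1$clinical$cohort == "validation"), 17)
  expect_true(file.exists(file.path(d1, "provenance.json")))

  # same seed -> identical clinical CSV checksum
  d2 <- withr::local_tempdir()
  generateCohort(cfg, d2, force = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, "clinical.csv"))),
                   unname(tools::md5sum(file.path(d2, "clinical.csv"))))
  # and bit-identical voxel data after round trip
  c1 <- readCase(b1$image_paths[1], b1$mask_paths[1])
  c2 <- readCase(file.path(d2, basename(b1$image_paths[1])),
                 file.path(d2, basename(b1$mask_paths[1])))
  expect_identical(voxelData(c1$volume), voxelData(c2$volume))

  # validation-only bundle
  cfg0 <- cohortConfig(n_train = 0, seed = 5,
                       grid_shape = c(40L, 40L, 20L))
  d3 <- withr::local_tempdir()
  b3 <- generateCohort(cfg0, d3, force = TRUE)
  expect_equal(unique(b3$clinical$cohort), "validation")
  expect_equal(nrow(b3$clinical), 17)
})

test_that("identical class parameters yield null per-feature AUCs", {
  # class separation is controllable: with identical texture parameters
  # for both classes, per-feature AUCs concentrate around 0.5
  same <- classTextureParams(mean_hu = 50, sd_hu = 30,
                             correlation_length = 2)
  cfg <- cohortConfig(n_train = 27, n_validation = 0,
                      responder_params = same, nonresponder_params = same,
                      seed = 31)
  d <- withr::local_tempdir()
  generateCohort(cfg, d, force = TRUE)
  se <- suppressWarnings(extractCohort(d))
  m <- SummarizedExperiment::assay(se, "features")
  labels <- SummarizedExperiment::colData(se)$response
  ok <- rowSums(is.na(m)) == 0 & apply(m, 1, sd) > 0
  aucs <- apply(m[ok, ], 1, function(v) aucWithP(v, labels)$auc)
  expect_gt(mean(aucs >= 0.2 & aucs <= 0.8), 0.95)
})
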