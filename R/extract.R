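#' Extract the full 476-feature vector for one case
#'
#' Runs the per-case pipeline: crop to the VOI bounding box (+ pad),
#' undecimated 3D wavelet decomposition on the native-grid crop, then
#' for each of the 9 component images isotropic resampling (default
#' 2 mm; mask nearest-neighbor, one shared interpolation plan) and
#' fixed-bin-width requantization (default 25), followed by histogram,
#' GLCM, GLRLM and GLSZM features. Shape features are computed once
#' from the resampled mask. Undefined features (e.g. correlation on a
#' single-gray-level component) come back as `NA`, flagged per feature,
#' never failing the case.
#'
#' @param vol a [CTVolume-class].
#' @param mask a [VOIMask-class] on the same grid.
#' @param target_spacing isotropic resampling target (mm), default 2.
#' @param bin_width quantization bin width, default 25.
#' @param basis wavelet basis, default "coif1".
#' @param pad crop margin in voxels, default 8.
#' @return named numeric(476) in catalog order.
#' @export
extractCase <- function(vol, mask, target_spacing = 2.0, bin_width = 25,
                        basis = "coif1", pad = 8L) {
  cr <- cropToMask(vol, mask, pad = pad)
  bank <- waveletDecompose(cr$volume, basis = basis)
  plan <- .resamplePlan(cr$volume, target_spacing)
  sp_out <- rep(target_spacing, 3)
  mask_rs <- array(as.integer(voxelData(cr$mask)[plan$plan$nn] > 0),
                   dim = plan$dims)
  if (sum(mask_rs) == 0)
    stop("VOI collapsed to zero voxels at ", target_spacing,
         " mm resampling")
  mask_rs <- VOIMask(mask_rs, sp_out, plan$origin)

  out <- rep(NA_real_, 476)
  catalog <- featureCatalog()
  names(out) <- catalog$id
  out[.SHAPE_IDS] <- shapeFeatures(mask_rs)

  for (cmp in .WAVELET_COMPONENTS) {
    img <- CTVolume(array(.applyTrilinear(componentImage(bank, cmp),
                                          plan$plan), dim = plan$dims),
                    sp_out, plan$origin)
    q <- quantizeVolume(img, mask_rs, bin_width)
    out[paste0(cmp, .HISTOGRAM_NAMES)] <-
      histogramFeatures(img, mask_rs, bin_width)
    out[paste0(cmp, .GLCM_NAMES)] <- glcmFeatures(buildGLCM(q))
    out[paste0(cmp, .GLRLM_NAMES)] <- glrlmFeatures(buildGLRLM(q))
    out[paste0(cmp, .GLSZM_NAMES)] <- glszmFeatures(buildGLSZM(q))
  }
  out
}

#' Extract features for a whole cohort into a SummarizedExperiment
#'
#' @param cohort_dir directory written by [generateCohort()] (or any
#'   directory holding `clinical.csv` plus
#'   `<case_id>_image.nii.gz` / `<case_id>_mask.nii.gz` pairs).
#' @param ... passed to [extractCase()].
#' @param verbose log per-case progress to stderr.
#' @return a [SummarizedExperiment::SummarizedExperiment] with one
#'   assay `features` (476 features x cases), `rowData` = the feature
#'   catalog and `colData` = the clinical table.
#' @export
extractCohort <- function(cohort_dir, ..., verbose = FALSE) {
  clin_path <- file.path(cohort_dir, "clinical.csv")
  if (!file.exists(clin_path)) stop("missing clinical table: ", clin_path)
  clin <- read.csv(clin_path, stringsAsFactors = FALSE)
  if (!nrow(clin)) stop("empty cohort: ", cohort_dir)
  feats <- matrix(NA_real_, nrow = 476, ncol = nrow(clin))
  failed <- character()
  for (k in seq_len(nrow(clin))) {
    cid <- clin$case_id[k]
    if (verbose) message("extracting ", cid)
    res <- tryCatch({
      cs <- readCase(file.path(cohort_dir, paste0(cid, "_image.nii.gz")),
                     file.path(cohort_dir, paste0(cid, "_mask.nii.gz")))
      extractCase(cs$volume, cs$mask, ...)
    }, error = function(e) {
      warning("case ", cid, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, cid) else feats[, k] <- res
  }
  if (length(failed))
    warning("feature extraction failed for: ", paste(failed, collapse = ", "))
  catalog <- featureCatalog()
  rownames(feats) <- catalog$id
  colnames(feats) <- clin$case_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feats),
    rowData = S4Vectors::DataFrame(catalog),
    colData = S4Vectors::DataFrame(clin, row.names = clin$case_id))
}

#' Write a feature SummarizedExperiment as CSV
#'
#' One row per case: `case_id` plus the 476 feature columns.
#'
#' @param se the SummarizedExperiment from [extractCohort()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFeatureCsv <- function(se, path) {
  m <- t(SummarizedExperiment::assay(se, "features"))
  df <- data.frame(case_id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
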