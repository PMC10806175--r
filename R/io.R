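#' Write a volume or mask as NIfTI
#'
#' @param x a [CTVolume-class] or [VOIMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeCaseNifti <- function(x, path) {
  img <- RNifti::asNifti(voxelData(x))
  RNifti::pixdim(img) <- voxelSpacing(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read one case (image + VOI mask)
#'
#' Reads a scalar 3D image and its mask (NIfTI), verifies that the two
#' grids agree (shape exactly; spacing within 1e-4 mm), and binarizes
#' the mask (> 0 becomes 1).
#'
#' @param image_path,mask_path NIfTI files (.nii / .nii.gz).
#' @return list with `volume` ([CTVolume-class]) and `mask`
#'   ([VOIMask-class]).
#' @export
readCase <- function(image_path, mask_path) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  if (length(dim(img)) != 3L || length(dim(msk)) != 3L)
    stop("expected 3D scalar images")
  sp_i <- RNifti::pixdim(img)[1:3]
  sp_m <- RNifti::pixdim(msk)[1:3]
  if (!identical(dim(img), dim(msk)) || any(abs(sp_i - sp_m) > 1e-4))
    stop(sprintf(
      "image/mask grid mismatch: image %s @ (%g, %g, %g) mm vs mask %s @ (%g, %g, %g) mm",
      paste(dim(img), collapse = "x"), sp_i[1], sp_i[2], sp_i[3],
      paste(dim(msk), collapse = "x"), sp_m[1], sp_m[2], sp_m[3]))
  if (!any(msk > 0)) stop("mask is empty: ", mask_path)
  list(volume = CTVolume(array(as.numeric(img), dim = dim(img)), sp_i),
       mask = VOIMask(array(as.numeric(msk), dim = dim(msk)), sp_i))
}
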