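#' Read a binary cord segmentation from a NIfTI-1 file
#'
#' Loads a 3-D binary mask and its voxel dimensions from the NIfTI header
#' into a [cord_mask]. Axial slices are assumed ordered inferior to
#' superior along the third axis.
#'
#' @param path Path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return A [cord_mask] object.
#' @export
read_cord_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vd <- abs(RNifti::pixdim(img))[1:3]
  cord_mask(array(as.numeric(img > 0.5), dim = dim(img)[1:3]), voxel_dims = vd)
}

#' Write a 3-D or 4-D volume as NIfTI-1
#'
#' @param voxels Numeric array (3-D mask/statistic volume or 4-D time series).
#' @param voxel_dims Voxel dimensions in mm (length 3; for 4-D data the
#'   fourth pixdim is `tr`).
#' @param path Output path, typically ending in `.nii.gz`.
#' @param tr Repetition time in seconds, written for 4-D images.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(voxels, voxel_dims, path, tr = NULL) {
  img <- RNifti::asNifti(voxels)
  pd <- voxel_dims[1:3]
  if (length(dim(voxels)) == 4) pd <- c(pd, if (is.null(tr)) 1 else tr)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write 6-column motion parameter files
#'
#' Motion parameters follow the common realignment convention: one row per
#' volume, whitespace-delimited, three translations (mm) then three
#' rotations (rad).
#'
#' @param path File path.
#' @return `read_motion_params`: a numeric matrix with 6 named columns.
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) stopf("motion parameter file must have 6 columns, found %d", ncol(m))
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' @rdname read_motion_params
#' @param motion Numeric matrix with 6 columns (translations mm, rotations rad).
#' @export
write_motion_params <- function(motion, path) {
  stopifnot(is.matrix(motion), ncol(motion) == 6)
  utils::write.table(motion, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
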