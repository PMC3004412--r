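#' Read a 3D volume from a NIfTI-1 file
#'
#' Loads the image as double-precision data with spacing taken from the
#' header zooms. A 4D file with a trailing singleton dimension is accepted
#' as 3D; genuinely 4D data is rejected. `range_peak` defaults to the data
#' maximum.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param range_peak optional override of the nominal intensity peak.
#' @return a [volume3d()].
#' @export
read_volume <- function(path, range_peak = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read volume: file not found: %s", path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  a <- array(as.numeric(img), dim = d)
  if (length(d) == 4L) {
    if (d[4] != 1L) {
      stop(sprintf("cannot read volume %s: 4D data with %d frames (expected 3D)",
                   path, d[4]), call. = FALSE)
    }
    dim(a) <- d[1:3]
  } else if (length(d) != 3L) {
    stop(sprintf("cannot read volume %s: %dD data (expected 3D)",
                 path, length(d)), call. = FALSE)
  }
  if (any(!is.finite(a))) {
    stop(sprintf("cannot read volume %s: non-finite intensities", path),
         call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)
  volume3d(a, spacing = spacing, range_peak = range_peak)
}

#' Write a volume to a NIfTI-1 file
#'
#' Writes single-precision data with the voxel spacing stored in the
#' header zooms.
#'
#' @param v a [volume3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype on-disk datatype (default `"float"`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "float") {
  stop_if_not_volume(v, "v")
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
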