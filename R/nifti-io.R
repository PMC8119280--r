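#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti for the package's containers: a 3-D map, a
#' `stat_map`'s values, or a `bold_series`' 4-D data.  Voxel size (and TR
#' for 4-D data) are recorded in the NIfTI pixdim.
#'
#' @param x A 3-D/4-D numeric array, `stat_map`, or `bold_series`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Voxel extents in mm.
#' @param tr_s Repetition time for 4-D data.
#' @return `write_volume` returns `path` invisibly; `read_volume` an
#'   array with a `pixdim` attribute.
#' @export
write_volume <- function(x, path, voxel_mm = c(1, 1, 1), tr_s = NULL) {
  if (inherits(x, "stat_map")) {
    if (!is.null(x$geometry)) voxel_mm <- x$geometry$voxel_mm
    x <- x$values
  } else if (inherits(x, "bold_series")) {
    voxel_mm <- x$geometry$voxel_mm
    tr_s <- x$geometry$tr_s
    x <- x$data
  }
  img <- RNifti::asNifti(x)
  pd <- if (length(dim(x)) == 4L) c(voxel_mm, tr_s %||% 1) else voxel_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}
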