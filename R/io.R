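#' Read a NIfTI-1 image
#'
#' Thin wrapper around [RNifti::readNifti()] returning a plain numeric array
#' (3D or 4D) with the NIfTI header retained in the `"geometry"` attribute so
#' that [write_image()] can round-trip it.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A 3D or 4D array with a `"geometry"` attribute.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a readable NIfTI-1 file: ",
                                           path, " (", conditionMessage(e), ")"))
  nd <- length(dim(img))
  if (nd != 3L && nd != 4L)
    stop("expected a 3D or 4D image, got ", nd, " dimensions")
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "geometry") <- RNifti::niftiHeader(img)
  arr
}

#' Write an array as a NIfTI-1 image
#'
#' @param x 3D or 4D numeric array, all values finite. A `voxel_map` is also
#'   accepted; its off-mask voxels are written as 0.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param geometry Optional NIfTI header (as returned in the `"geometry"`
#'   attribute of [read_image()]) or a template image to copy geometry from.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, geometry = NULL) {
  if (inherits(x, "voxel_map")) {
    v <- x$values
    v[!x$mask] <- 0
    x <- v
  }
  if (is.null(geometry)) geometry <- attr(x, "geometry")
  if (!all(is.finite(x))) stop("refusing to write non-finite voxel values")
  img <- if (is.null(geometry)) RNifti::asNifti(array(x, dim = dim(x)))
         else RNifti::asNifti(array(x, dim = dim(x)), reference = geometry)
  ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("could not write image to ", path)
  invisible(path)
}

#' Read a 3D mask image as a logical array
#'
#' Voxels with values different from 0 (beyond a small tolerance) are `TRUE`.
#'
#' @inheritParams read_image
#' @return 3D logical array with the image's `"geometry"` attribute.
#' @export
read_mask <- function(path) {
  arr <- read_image(path)
  if (length(dim(arr)) != 3L) stop("mask must be a 3D image")
  out <- array(abs(arr) > 1e-6, dim = dim(arr))
  attr(out, "geometry") <- attr(arr, "geometry")
  out
}
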