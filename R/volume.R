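#' 3D image volume with physical geometry
#'
#' An `image_volume` is a 3D numeric array with per-axis voxel spacing (mm)
#' and a world-space origin, the coordinates of the center of voxel
#' `[1, 1, 1]`. It is the container for CT-like scalar volumes throughout the
#' pipeline.
#'
#' @param data 3D numeric array of voxel values (finite).
#' @param spacing_mm numeric length-3 vector of voxel sizes in mm, all > 0.
#' @param origin_mm numeric length-3 world coordinate of the first voxel
#'   center. Default `c(0, 0, 0)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite values")
  if (any(!is.finite(data)))
    stop("volume contains non-finite values")
  structure(
    list(data = data, spacing_mm = spacing_mm, origin_mm = as.numeric(origin_mm)),
    class = "image_volume"
  )
}

#' Binary region-of-interest mask
#'
#' A `roi_mask` shares geometry with an [image_volume()]; voxel values are 1
#' inside the tumor and 0 outside.
#'
#' @param data 3D array of 0/1 values.
#' @inheritParams image_volume
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be 0/1")
  v <- image_volume(data + 0, spacing_mm, origin_mm)
  class(v) <- c("roi_mask", "image_volume")
  v
}

#' @exportS3Method print image_volume
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm\n",
              class(x)[1L], d[1L], d[2L], d[3L],
              paste(format(x$spacing_mm, digits = 3), collapse = " x ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

stopifnot_same_geometry <- function(v, m) {
  if (!same_geometry(v, m))
    stop("volume and mask geometry mismatch (shape/spacing/origin must agree)")
}

n_mask_voxels <- function(m) sum(m$data != 0)

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving voxel spacing. `read_volume` returns
#' an [image_volume()]; `read_mask` additionally binarizes (> 0.5).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param v,m objects to write.
#' @return `read_volume`/`read_mask` return the parsed object; writers return
#'   the path invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  image_volume(arr, RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  roi_mask((v$data > 0.5) + 0, v$spacing_mm, v$origin_mm)
}

#' @rdname read_volume
#' @export
write_mask <- function(m, path) write_volume(m, path)
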