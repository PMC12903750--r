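#' Resample a volume/mask pair to isotropic spacing
#'
#' Brings a CT volume acquired with anisotropic spacing (e.g. 1-5 mm slices)
#' to a uniform grid, the standard first step before texture extraction. The
#' volume is interpolated trilinearly; the mask by nearest neighbor and
#' re-binarized so it stays a 0/1 label image. The world extent spanned by
#' the voxel centers is preserved to within one voxel.
#'
#' @param v an [image_volume()].
#' @param m an [roi_mask()] with identical geometry.
#' @param target_mm target isotropic spacing in mm (default 1).
#' @return list with elements `volume` and `mask`.
#' @export
resample_isotropic <- function(v, m, target_mm = 1.0) {
  stopifnot_same_geometry(v, m)
  if (target_mm <= 0) stop("target_mm must be > 0")
  grids <- lapply(1:3, function(ax) {
    extent <- (dim(v$data)[ax] - 1L) * v$spacing_mm[ax]
    n_new <- max(1L, as.integer(round(extent / target_mm)) + 1L)
    (seq_len(n_new) - 1L) * target_mm / v$spacing_mm[ax] + 1  # in old voxel units
  })
  vol_out <- interp_3d(v$data, grids, method = "linear")
  msk_out <- interp_3d(m$data, grids, method = "nearest")
  msk_out <- (msk_out > 0.5) + 0
  sp <- rep(target_mm, 3L)
  list(volume = image_volume(vol_out, sp, v$origin_mm),
       mask = roi_mask(msk_out, sp, v$origin_mm))
}

# Separable interpolation on a regular grid. `grids` gives, per axis, the
# sample positions in (1-based) source voxel units; positions are clamped to
# the array. Linear interpolation is separable, so applying it axis by axis
# equals trilinear interpolation.
interp_3d <- function(a, grids, method = c("linear", "nearest")) {
  method <- match.arg(method)
  for (ax in 1:3) {
    pos <- pmin(pmax(grids[[ax]], 1), dim(a)[ax])
    if (method == "nearest") {
      i0 <- pmin(pmax(round(pos), 1), dim(a)[ax])
      a <- index_axis(a, ax, i0)
    } else {
      i0 <- pmin(floor(pos), dim(a)[ax] - ifelse(dim(a)[ax] > 1L, 1L, 0L))
      i0 <- pmax(i0, 1L)
      w <- pos - i0
      lo <- index_axis(a, ax, i0)
      hi <- index_axis(a, ax, pmin(i0 + 1L, dim(a)[ax]))
      a <- sweep_axis_combine(lo, hi, w, ax)
    }
  }
  a
}

index_axis <- function(a, ax, idx) {
  switch(ax,
    `1` = a[idx, , , drop = FALSE],
    `2` = a[, idx, , drop = FALSE],
    `3` = a[, , idx, drop = FALSE])
}

sweep_axis_combine <- function(lo, hi, w, ax) {
  dm <- dim(lo)
  wfull <- switch(ax,
    `1` = array(w, dim = dm),
    `2` = array(rep(w, each = dm[1L]), dim = dm),
    `3` = array(rep(w, each = dm[1L] * dm[2L]), dim = dm))
  lo * (1 - wfull) + hi * wfull
}

#' Gaussian denoising in physical units
#'
#' Separable Gaussian convolution with a sigma given in mm and converted to
#' voxels per axis by the volume's spacing, so smoothing is isotropic in
#' world space even on anisotropic grids. `sigma_mm = 0` is the identity.
#'
#' @param v an [image_volume()].
#' @param sigma_mm Gaussian standard deviation in mm (>= 0).
#' @return the smoothed [image_volume()].
#' @export
denoise_gaussian <- function(v, sigma_mm) {
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || is.na(sigma_mm) || sigma_mm < 0)
    stop("sigma_mm must be a single non-negative number")
  if (sigma_mm == 0) return(v)
  kernels <- lapply(1:3, function(ax) gaussian_kernel_1d(sigma_mm / v$spacing_mm[ax]))
  image_volume(conv_separable(v$data, kernels), v$spacing_mm, v$origin_mm)
}

#' Rescale intensities to the 0-255 range
#'
#' Affine rescaling so the observed minimum maps to 0 and the maximum to 255.
#' When a mask is supplied the min/max are computed inside the mask and
#' values elsewhere are clipped into `[0, 255]` after mapping. A constant
#' input (no dynamic range) maps to all zeros.
#'
#' @param v an [image_volume()].
#' @param m optional [roi_mask()] restricting the range computation.
#' @return the rescaled [image_volume()].
#' @export
normalize_intensity <- function(v, m = NULL) {
  vals <- if (is.null(m)) v$data else {
    stopifnot_same_geometry(v, m)
    v$data[m$data != 0]
  }
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) {
    return(image_volume(array(0, dim = dim(v$data)), v$spacing_mm, v$origin_mm))
  }
  out <- (v$data - lo) / (hi - lo) * 255
  out[out < 0] <- 0
  out[out > 255] <- 255
  image_volume(out, v$spacing_mm, v$origin_mm)
}
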