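#' Discretize in-mask intensities into gray levels
#'
#' Equal-width binning of the intensities inside the ROI into levels
#' `1..n_bins`; voxels outside the mask are level 0. All gray-level matrix
#' features (GLCM, GLRLM, GLSZM) operate on the result. A constant ROI has a
#' single occupied level (`n_levels = 1`).
#'
#' @param v an [image_volume()].
#' @param m an [roi_mask()], nonempty.
#' @param n_bins number of equal-width bins (>= 2).
#' @return object of class `quantized_roi`: list with `levels` (integer 3D
#'   array), `n_levels` (highest occupied level), `bin_edges`, `spacing_mm`.
#' @export
discretize <- function(v, m, n_bins = 32L) {
  stopifnot_same_geometry(v, m)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  inm <- m$data != 0
  if (!any(inm)) stop("empty mask")
  vals <- v$data[inm]
  lo <- min(vals); hi <- max(vals)
  lv <- array(0L, dim = dim(v$data))
  if (hi <= lo) {
    lv[inm] <- 1L
    edges <- c(lo - 0.5, lo + 0.5)
  } else {
    width <- (hi - lo) / n_bins
    lev <- pmin(floor((vals - lo) / width) + 1L, n_bins)
    lv[inm] <- as.integer(lev)
    edges <- lo + width * (0:n_bins)
  }
  structure(list(levels = lv, n_levels = max(lv), bin_edges = edges,
                 spacing_mm = v$spacing_mm),
            class = "quantized_roi")
}

#' @exportS3Method print quantized_roi
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %s voxels in mask, %d gray levels\n",
              sum(x$levels > 0), x$n_levels))
  invisible(x)
}
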