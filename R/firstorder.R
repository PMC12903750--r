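#' First-order intensity statistics of a ROI
#'
#' Statistics of the in-mask intensity distribution: mean, population
#' variance, skewness, Fisher (excess) kurtosis, median, minimum, maximum,
#' range, energy (sum of squares), histogram entropy (on the discretized
#' intensities, bits) and the 10th/90th percentiles. A constant ROI has
#' variance, skewness, kurtosis and entropy 0.
#'
#' @param v an [image_volume()].
#' @param m an [roi_mask()], nonempty.
#' @param n_bins bins for the entropy histogram (default 32).
#' @return named numeric vector with `firstorder_*` names.
#' @export
first_order_features <- function(v, m, n_bins = 32L) {
  stopifnot_same_geometry(v, m)
  x <- v$data[m$data != 0]
  if (length(x) == 0L) stop("empty mask")
  n <- length(x)
  mu <- mean(x)
  v2 <- mean((x - mu)^2)
  sdev <- sqrt(v2)
  skew <- if (sdev > 0) mean((x - mu)^3) / sdev^3 else 0
  kurt <- if (sdev > 0) mean((x - mu)^4) / v2^2 - 3 else 0
  q <- discretize(image_volume(array(x, c(n, 1, 1)), c(1, 1, 1)),
                  roi_mask(array(1, c(n, 1, 1)), c(1, 1, 1)), n_bins = n_bins)
  p <- tabulate(q$levels[q$levels > 0], nbins = q$n_levels) / n
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  c(firstorder_Mean = mu,
    firstorder_Variance = v2,
    firstorder_Skewness = skew,
    firstorder_Kurtosis = kurt,
    firstorder_Median = stats::median(x),
    firstorder_Minimum = min(x),
    firstorder_Maximum = max(x),
    firstorder_Range = max(x) - min(x),
    firstorder_Energy = sum(x^2),
    firstorder_Entropy = ent,
    firstorder_Percentile10 = unname(stats::quantile(x, 0.10)),
    firstorder_Percentile90 = unname(stats::quantile(x, 0.90)))
}
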