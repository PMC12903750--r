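#' Build a points-based nomogram from a logistic model
#'
#' Standard regression-nomogram scaling: variable `j` at value `x`
#' contributes `100 * |b_j| * (x - ref_j) / M` points, where `b_j` is the
#' raw-scale coefficient, `ref_j` is the risk-minimizing end of the
#' variable's observed range and `M = max_k |b_k| * range_k`, so the most
#' influential variable spans exactly 0-100 points. Total points map
#' affinely to the linear predictor and through the logistic function to
#' the predicted probability, making the chart round-trip-consistent with
#' the model.
#'
#' @param model a logistic `trained_model` (from [fit_classifier()] or the
#'   combined signature of [fit_logistic_signatures()]).
#' @param data data.frame holding the training values of the model's
#'   variables (defines each variable's range).
#' @return object of class `nomogram_spec`: per-variable reference value,
#'   raw coefficient and points-per-unit, plus the total-points to
#'   linear-predictor mapping.
#' @export
build_nomogram <- function(model, data) {
  if (!inherits(model, "trained_model") || model$algorithm != "logistic")
    stop("nomogram requires a logistic trained_model")
  feats <- model$features
  missing <- setdiff(feats, names(data))
  if (length(missing) > 0L)
    stop("data lacks model variable(s): ", paste(missing, collapse = ", "))
  co <- if (inherits(model$fit, "ridge_logistic")) model$fit$beta
        else as.numeric(stats::coef(model$fit))
  b0_std <- co[1L]; b_std <- co[-1L]
  # back-transform to the raw variable scale
  b_raw <- b_std / model$scale
  b0_raw <- b0_std - sum(b_std * model$center / model$scale)
  rng <- vapply(feats, function(f) range(data[[f]]), numeric(2L))
  span <- rng[2L, ] - rng[1L, ]
  infl <- abs(b_raw) * span
  if (all(infl == 0)) stop("degenerate model: no risk variation to map")
  M <- max(infl)
  ref <- ifelse(b_raw >= 0, rng[1L, ], rng[2L, ])
  structure(list(variables = feats, beta = b_raw, intercept = b0_raw,
                 ref = ref, range_low = rng[1L, ], range_high = rng[2L, ],
                 scale_max = M,
                 lp_offset = b0_raw + sum(b_raw * ref)),
            class = "nomogram_spec")
}

#' @exportS3Method print nomogram_spec
print.nomogram_spec <- function(x, ...) {
  cat("<nomogram_spec> variables:", paste(x$variables, collapse = ", "), "\n")
  for (i in seq_along(x$variables)) {
    pts <- 100 * abs(x$beta[i]) * (x$range_high[i] - x$range_low[i]) /
      x$scale_max
    cat(sprintf("  %-20s range [%g, %g] -> 0-%.1f points\n", x$variables[i],
                x$range_low[i], x$range_high[i], pts))
  }
  invisible(x)
}

#' Read a prediction off the nomogram
#'
#' Values outside the range the chart was built on are clipped with a
#' warning (a paper chart cannot extrapolate); a missing variable is an
#' error naming it.
#'
#' @param spec a [build_nomogram()] result.
#' @param values named list / one-row data.frame of variable values.
#' @return list with `points` (named, per variable), `total_points`,
#'   `probability`.
#' @export
nomogram_predict <- function(spec, values) {
  stopifnot(inherits(spec, "nomogram_spec"))
  values <- as.list(values)
  missing <- setdiff(spec$variables, names(values))
  if (length(missing) > 0L)
    stop("missing variable(s): ", paste(missing, collapse = ", "))
  pts <- numeric(length(spec$variables))
  names(pts) <- spec$variables
  for (i in seq_along(spec$variables)) {
    v <- spec$variables[i]
    x <- as.numeric(values[[v]])
    if (x < spec$range_low[i] || x > spec$range_high[i]) {
      warning(v, " outside the nomogram range; clipping")
      x <- min(max(x, spec$range_low[i]), spec$range_high[i])
    }
    pts[i] <- 100 * abs(spec$beta[i]) * abs(x - spec$ref[i]) / spec$scale_max
  }
  total <- sum(pts)
  lp <- spec$lp_offset + spec$scale_max / 100 * total
  list(points = pts, total_points = total,
       probability = as.numeric(stats::plogis(lp)))
}
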