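#' Extraction configuration
#'
#' @param families feature families to compute; subset of
#'   `c("firstorder", "shape", "glcm", "glrlm", "glszm")`.
#' @param filters image transforms to extract intensity families from;
#'   `"original"` plus any of [apply_image_filters()]'s filters. Shape
#'   features are geometry-only and always computed from the original mask.
#' @param n_bins gray levels for discretization (default 32).
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(families = c("firstorder", "shape", "glcm",
                                           "glrlm", "glszm"),
                              filters = "original", n_bins = 32L) {
  known <- c("firstorder", "shape", "glcm", "glrlm", "glszm")
  bad <- setdiff(families, known)
  if (length(bad) > 0L)
    stop("unknown families: ", paste(bad, collapse = ", "))
  badf <- setdiff(filters, c("original", SUPPORTED_FILTERS))
  if (length(badf) > 0L)
    stop("unknown filters: ", paste(badf, collapse = ", "))
  structure(list(families = families, filters = filters,
                 n_bins = as.integer(n_bins)),
            class = "extraction_config")
}

#' Extract the full radiomic feature vector for one case
#'
#' Computes the union of the enabled feature families over the enabled image
#' transforms, with the canonical naming grammar
#' `transform_family_statistic` (e.g. `original_glcm_Contrast`,
#' `wavelet-LLH_glrlm_LongRunEmphasis`). Output order is deterministic:
#' transforms in configuration order, families in configuration order.
#'
#' @param v a preprocessed [image_volume()].
#' @param m an [roi_mask()].
#' @param config an [extraction_config()].
#' @return named numeric vector.
#' @export
extract_case_features <- function(v, m, config = extraction_config()) {
  stopifnot(inherits(config, "extraction_config"))
  stopifnot_same_geometry(v, m)
  images <- list(original = v)
  extra <- setdiff(config$filters, "original")
  if (length(extra) > 0L) {
    images <- c(images, apply_image_filters(v, extra))
    if (!"original" %in% config$filters) images$original <- NULL
    if ("original" %in% config$filters)
      images <- c(images["original"], images[setdiff(names(images), "original")])
  }
  out <- numeric(0)
  for (tr in names(images)) {
    vi <- images[[tr]]
    q <- NULL
    for (fam in config$families) {
      fv <- tryCatch(switch(fam,
        firstorder = first_order_features(vi, m, n_bins = config$n_bins),
        shape = if (tr == "original") shape_features(m) else NULL,
        glcm = ,
        glrlm = ,
        glszm = {
          if (is.null(q)) q <- discretize(vi, m, n_bins = config$n_bins)
          switch(fam, glcm = glcm_features(q), glrlm = glrlm_features(q),
                 glszm = glszm_features(q))
        }),
        error = function(e) stop("family ", fam, " on transform ", tr, ": ",
                                 conditionMessage(e), call. = FALSE))
      if (is.null(fv)) next
      names(fv) <- paste0(tr, "_", names(fv))
      out <- c(out, fv)
    }
  }
  out
}

#' Extract features for a list of cases into a feature table
#'
#' @param cases list of synthetic or loaded cases, each with elements
#'   `case_id`, `center_id`, `cohort`, `label`, `volume`, `mask`.
#' @param config an [extraction_config()].
#' @return data.frame feature table (one row per case).
#' @export
extract_cohort_features <- function(cases, config = extraction_config()) {
  rows <- lapply(cases, function(cs) {
    fv <- extract_case_features(cs$volume, cs$mask, config)
    cbind(data.frame(case_id = cs$case_id, center = cs$center_id,
                     cohort = cs$cohort, label = cs$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  do.call(rbind, rows)
}
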