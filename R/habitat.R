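#' Voxel-level local texture descriptor map
#'
#' For every in-mask voxel: its own intensity plus statistics of its
#' `(2r+1)^3` neighborhood intersected with the mask -- local mean, local
#' (population) variance, local histogram entropy and local GLCM contrast
#' (mean squared gray-level difference over distance-1 voxel pairs inside
#' the window). The voxel's own intensity is carried as the first channel
#' because window statistics are spatially blurred across habitat
#' interfaces, while the center intensity remains a pure sample of its
#' habitat. Descriptors are z-scored across the tumor before clustering;
#' channels with zero variance map to 0. All window statistics are computed
#' by box filtering, so the map is deterministic and scales linearly with
#' volume size.
#'
#' @param v an [image_volume()].
#' @param m an [roi_mask()], nonempty.
#' @param window_radius neighborhood radius in voxels (>= 1, default 1: at 1 mm isotropic resampling and desk-scale tumors, larger windows blur across habitat interfaces).
#' @param n_bins gray levels for the entropy/contrast channels (default 16).
#' @return object of class `voxel_feature_map`: list with `coords` (n x 3
#'   voxel indices), `index` (linear indices), `features` (n x 5 z-scored
#'   matrix), `raw` (pre-scaling matrix), `intensity` (raw voxel values),
#'   `window_radius`, `dim`, `spacing_mm`.
#' @export
compute_voxel_feature_map <- function(v, m, window_radius = 1L, n_bins = 16L) {
  if (window_radius < 1L) stop("window_radius must be >= 1")
  stopifnot_same_geometry(v, m)
  inm <- m$data != 0
  if (!any(inm)) stop("empty mask")
  r <- as.integer(window_radius)
  x <- v$data * inm
  cnt <- box_sum(inm + 0, r)
  s1 <- box_sum(x, r)
  s2 <- box_sum(x^2, r)
  loc_mean <- s1 / pmax(cnt, 1)
  loc_var <- pmax(s2 / pmax(cnt, 1) - loc_mean^2, 0)

  q <- discretize(v, m, n_bins = n_bins)
  lv <- q$levels
  # local histogram entropy from per-level box counts
  ent <- array(0, dim = dim(lv))
  for (g in seq_len(q$n_levels)) {
    cg <- box_sum((lv == g) + 0, r)
    p <- cg / pmax(cnt, 1)
    contrib <- ifelse(p > 0, -p * log2(p), 0)
    ent <- ent + contrib
  }
  # local contrast: box-filtered squared level differences over 13 directions
  num <- array(0, dim = dim(lv))
  den <- array(0, dim = dim(lv))
  dirs <- directions_13()
  for (rr in seq_len(nrow(dirs))) {
    sh <- shift_array(lv, dirs[rr, ], fill = 0L)
    ok <- (lv > 0L) & (sh > 0L)
    d2 <- (lv - sh)^2 * ok
    num <- num + box_sum(d2 + 0, r)
    den <- den + box_sum(ok + 0, r)
  }
  loc_contrast <- num / pmax(den, 1)

  idx <- which(inm)
  raw <- cbind(intensity = v$data[idx],
               local_mean = loc_mean[idx],
               local_variance = loc_var[idx],
               local_entropy = ent[idx],
               local_contrast = loc_contrast[idx])
  feats <- apply(raw, 2L, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (!is.matrix(feats)) feats <- matrix(feats, nrow = length(idx))
  structure(list(coords = voxel_coords(idx, dim(v$data)), index = idx,
                 features = feats, raw = raw, intensity = v$data[idx],
                 window_radius = r, dim = dim(v$data),
                 spacing_mm = v$spacing_mm),
            class = "voxel_feature_map")
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion, normalized by
#' degrees of freedom: `(B/(k-1)) / (W/(n-k))`.
#'
#' @param X numeric matrix (observations x variables).
#' @param labels integer cluster labels.
#' @return the CH score (single number).
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n <- nrow(X)
  if (k < 2L || k >= n) return(NA_real_)
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (c in seq_len(k)) {
    Xi <- X[labels == c, , drop = FALSE]
    ci <- colMeans(Xi)
    B <- B + nrow(Xi) * sum((ci - grand)^2)
    W <- W + sum(sweep(Xi, 2L, ci, "-")^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Partition a tumor into habitats by k-means with CH model selection
#'
#' Runs k-means (best of `nstart` restarts) on the weighted z-scored voxel
#' descriptors for every `k` in `[k_min, k_max]`, scores each partition
#' with the Calinski-Harabasz index, and keeps the `k` with the highest
#' score (smallest `k` on ties). Habitat labels are renumbered `1..K` by
#' ascending within-habitat mean raw intensity so indices are stable across
#' restarts and cases.
#'
#' The default channel weights (3, 2, 1, 1, 1 for intensity, local mean,
#' variance, entropy, contrast) make the phenotype axes dominate: the
#' second-order window channels respond to habitat interfaces as strongly
#' as to interiors, and at equal weight interface voxels seed spurious
#' clusters and drag centers off the habitat modes.
#'
#' @param fmap a [compute_voxel_feature_map()] result.
#' @param k_min,k_max candidate cluster-count range (defaults 2 and 10).
#' @param seed integer seed; all restarts derive from it.
#' @param nstart k-means restarts per k (default 10).
#' @param channel_weights per-channel multipliers applied to the z-scored
#'   descriptors before clustering.
#' @return object of class `habitat_map`: list with `labels` (3D integer
#'   array, 0 outside mask), `k` (selected count), `ch_scores` (named vector
#'   over candidate k), `dim`, `spacing_mm`.
#' @export
partition_habitats <- function(fmap, k_min = 2L, k_max = 10L, seed = 1L,
                               nstart = 10L,
                               channel_weights = c(3, 2, 1, 1, 1)) {
  stopifnot(inherits(fmap, "voxel_feature_map"))
  if (length(channel_weights) != ncol(fmap$features))
    stop("channel_weights must match the descriptor channel count")
  X <- sweep(fmap$features, 2L, channel_weights, "*")
  n_distinct <- nrow(unique(X))
  if (n_distinct < k_min)
    stop("fewer distinct descriptor vectors (", n_distinct,
         ") than k_min (", k_min, ")")
  if (n_distinct < k_max) {
    warning("fewer distinct descriptor vectors than k_max; lowering k_max to ",
            n_distinct)
    k_max <- n_distinct
  }
  ks <- k_min:k_max
  ch <- stats::setNames(rep(NA_real_, length(ks)), ks)
  fits <- vector("list", length(ks))
  for (ii in seq_along(ks)) {
    k <- ks[ii]
    set.seed(seed * 1000L + k)
    fits[[ii]] <- suppressWarnings(
      stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L))
    ch[ii] <- calinski_harabasz(X, fits[[ii]]$cluster)
  }
  best <- which.max(ch)  # which.max returns the first (smallest k) on ties
  kstar <- ks[best]
  cl <- fits[[best]]$cluster
  # renumber by ascending mean raw intensity
  mu <- vapply(seq_len(kstar), function(c) mean(fmap$intensity[cl == c]),
               numeric(1L))
  remap <- match(seq_len(kstar), order(mu))
  cl <- remap[cl]
  labels <- array(0L, dim = fmap$dim)
  labels[fmap$index] <- cl
  structure(list(labels = labels, k = kstar, ch_scores = ch,
                 dim = fmap$dim, spacing_mm = fmap$spacing_mm),
            class = "habitat_map")
}

#' @exportS3Method print habitat_map
print.habitat_map <- function(x, ...) {
  cat(sprintf("<habitat_map> K = %d habitats over %d voxels (CH-selected)\n",
              x$k, sum(x$labels > 0)))
  invisible(x)
}

#' Per-habitat radiomic features
#'
#' Reuses the whole-tumor feature machinery on each habitat submask:
#' first-order plus GLCM/GLRLM/GLSZM features with names suffixed `_habK`,
#' plus each habitat's volume fraction. Habitats smaller than
#' `min_voxels` yield `NA` feature values (flagged missing, imputed
#' downstream), keeping the schema identical across cases.
#'
#' @param v an [image_volume()].
#' @param h a [partition_habitats()] result (or any `habitat_map`).
#' @param n_bins gray levels for texture discretization.
#' @param min_voxels minimum habitat size for texture validity (default 10).
#' @param families families to compute per habitat.
#' @return named numeric vector.
#' @export
extract_habitat_features <- function(v, h, n_bins = 32L, min_voxels = 10L,
                                     families = c("firstorder", "glcm",
                                                  "glrlm", "glszm")) {
  stopifnot(inherits(h, "habitat_map"))
  if (!all(dim(v$data) == h$dim))
    stop("label map / volume geometry mismatch")
  n_tot <- sum(h$labels > 0L)
  out <- numeric(0)
  for (k in seq_len(h$k)) {
    sub <- (h$labels == k) + 0
    nk <- sum(sub)
    if (nk >= min_voxels) {
      mk <- roi_mask(sub, v$spacing_mm, v$origin_mm)
      fv <- numeric(0)
      q <- if (any(c("glcm", "glrlm", "glszm") %in% families))
        discretize(v, mk, n_bins = n_bins) else NULL
      for (fam in families) {
        fv <- c(fv, switch(fam,
          firstorder = first_order_features(v, mk, n_bins = n_bins),
          glcm = glcm_features(q),
          glrlm = glrlm_features(q),
          glszm = glszm_features(q)))
      }
    } else {
      # schema from a degenerate computation on a stub, values NA
      fv <- habitat_feature_schema(families)
    }
    names(fv) <- paste0("original_", names(fv), "_hab", k)
    fv <- c(fv, stats::setNames(nk / n_tot,
                                paste0("habitat_volume_fraction_hab", k)))
    out <- c(out, fv)
  }
  out
}

habitat_feature_schema <- function(families) {
  v1 <- image_volume(array(c(1, 2, 3, 4) + 0, c(4, 1, 1)), c(1, 1, 1))
  m1 <- roi_mask(array(1, c(4, 1, 1)), c(1, 1, 1))
  q1 <- discretize(v1, m1, 2L)
  fv <- numeric(0)
  for (fam in families) {
    fv <- c(fv, switch(fam,
      firstorder = first_order_features(v1, m1),
      glcm = glcm_features(q1),
      glrlm = glrlm_features(q1),
      glszm = glszm_features(q1)))
  }
  fv[] <- NA_real_
  fv
}

#' Harmonize the habitat count across a cohort
#'
#' Strategy `"global-mode"` (default): the common habitat count `K*` is the
#' modal per-case CH optimum across the supplied cases and every case is
#' re-clustered at `K*`. Strategy `"per-case"` keeps each case's own optimum;
#' features then align by the intensity-ranked habitat index.
#'
#' @param fmaps named list of [compute_voxel_feature_map()] results.
#' @param strategy `"global-mode"` or `"per-case"`.
#' @param k_min,k_max,seed,nstart passed to [partition_habitats()].
#' @return list with `k_star` (NA for per-case), `maps` (named list of
#'   `habitat_map`s), `optima` (per-case CH-optimal k).
#' @export
harmonize_habitat_count <- function(fmaps, strategy = c("global-mode",
                                                        "per-case"),
                                    k_min = 2L, k_max = 10L, seed = 1L,
                                    nstart = 10L) {
  strategy <- match.arg(strategy)
  maps <- lapply(seq_along(fmaps), function(i)
    partition_habitats(fmaps[[i]], k_min, k_max, seed = seed + i,
                       nstart = nstart))
  names(maps) <- names(fmaps)
  optima <- vapply(maps, function(m) m$k, integer(1L))
  if (strategy == "per-case")
    return(list(k_star = NA_integer_, maps = maps, optima = optima))
  tab <- table(optima)
  k_star <- as.integer(names(tab)[which.max(tab)])
  maps <- lapply(seq_along(fmaps), function(i) {
    m <- partition_habitats(fmaps[[i]], k_min = k_star, k_max = k_star,
                            seed = seed + i, nstart = nstart)
    m$ch_scores <- maps[[i]]$ch_scores
    m
  })
  names(maps) <- names(fmaps)
  list(k_star = k_star, maps = maps, optima = optima)
}
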