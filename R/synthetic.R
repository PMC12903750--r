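# Synthetic multi-center phantom cohort with planted habitat structure.
# Every downstream stage (preprocessing, texture features, habitat mapping,
# modeling, evaluation) is validated against the ground truth these
# generators plant: habitat geometry and intensities, center batch effects,
# and a logistic outcome model on ground-truth habitat summaries.

#' Phantom specification
#'
#' Describes one synthetic tumor: an ellipsoid of `n_habitats` spatially
#' contiguous subregions (concentric shells by default, Voronoi cells of
#' random seeds as an alternative), each filled with spatially correlated
#' Gaussian texture at its own mean/sd, plus global additive noise.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param spacing_mm voxel size per axis in mm.
#' @param n_habitats planted habitat count `K_true` (>= 1).
#' @param habitat_means per-habitat mean intensity (innermost first);
#'   pairwise distinct when `n_habitats > 1`.
#' @param habitat_sds per-habitat texture standard deviation.
#' @param correlation_length_vox texture correlation length (voxels).
#' @param tumor_radius_mm ellipsoid semi-axes in mm (length 1 or 3).
#' @param noise_sd additive white-noise sd on top of the texture.
#' @param geometry `"shells"` (default) or `"voronoi"`.
#' @param seed integer seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         spacing_mm = c(1, 1, 1),
                         n_habitats = 4L,
                         habitat_means = c(40, 90, 150, 210),
                         habitat_sds = rep(5, length(habitat_means)),
                         correlation_length_vox = 1.5,
                         tumor_radius_mm = 12,
                         noise_sd = 2,
                         geometry = c("shells", "voronoi"),
                         seed = 1L) {
  geometry <- match.arg(geometry)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(tumor_radius_mm) == 1L) tumor_radius_mm <- rep(tumor_radius_mm, 3L)
  if (n_habitats < 1L) stop("n_habitats must be >= 1")
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (length(habitat_means) != n_habitats || length(habitat_sds) != n_habitats)
    stop("habitat_means / habitat_sds must have length n_habitats")
  if (n_habitats > 1L && anyDuplicated(habitat_means))
    stop("habitat mean intensities must be pairwise distinct")
  half_extent <- (grid_shape - 1) / 2 * spacing_mm
  bad <- which(tumor_radius_mm > half_extent)
  if (length(bad) > 0L)
    stop("tumor exceeds grid along axis ", paste(bad, collapse = ", "),
         " (radius ", paste(round(tumor_radius_mm[bad], 1), collapse = ", "),
         " mm > half extent ",
         paste(round(half_extent[bad], 1), collapse = ", "), " mm)")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = spacing_mm, n_habitats = as.integer(n_habitats),
                 habitat_means = habitat_means, habitat_sds = habitat_sds,
                 correlation_length_vox = correlation_length_vox,
                 tumor_radius_mm = tumor_radius_mm, noise_sd = noise_sd,
                 geometry = geometry, seed = as.integer(seed)),
            class = "phantom_spec")
}

# correlated unit-variance Gaussian field: filtered white noise rescaled
correlated_field <- function(dm, corr_len) {
  w <- array(stats::rnorm(prod(dm)), dim = dm)
  if (corr_len > 0) {
    k <- gaussian_kernel_1d(corr_len)
    w <- conv_separable(w, list(k, k, k))
    s <- stats::sd(as.vector(w))
    if (s > 0) w <- w / s
  }
  w
}

#' Generate one phantom tumor
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([image_volume()]), `mask` ([roi_mask()]) and
#'   `truth_habitats` (a `habitat_map` holding the planted labels).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dm <- spec$grid_shape
  ctr <- (dm + 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(dm[a]) - ctr[a]) * spec$spacing_mm[a] /
                                   spec$tumor_radius_mm[a])^2)
  rho2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  rho <- sqrt(rho2)
  inm <- rho <= 1
  mask <- roi_mask(inm + 0, spec$spacing_mm)
  K <- spec$n_habitats

  labels <- array(0L, dim = dm)
  if (K == 1L) {
    labels[inm] <- 1L
  } else if (spec$geometry == "shells") {
    # equal-volume concentric shells, innermost = habitat 1
    qs <- stats::quantile(rho[inm], probs = seq_len(K - 1L) / K)
    labels[inm] <- as.integer(findInterval(rho[inm], qs) + 1L)
  } else {
    idx <- which(inm)
    seeds <- sample(idx, K)
    co <- voxel_coords(which(inm), dm)
    sco <- voxel_coords(seeds, dm)
    co_mm <- sweep(co, 2L, spec$spacing_mm, "*")
    sco_mm <- sweep(sco, 2L, spec$spacing_mm, "*")
    d2 <- outer(rowSums(co_mm^2), rep(1, K)) +
      outer(rep(1, nrow(co_mm)), rowSums(sco_mm^2)) -
      2 * co_mm %*% t(sco_mm)
    labels[inm] <- max.col(-d2)
  }

  vol <- array(0, dim = dm)
  for (k in seq_len(K)) {
    sel <- labels == k
    if (!any(sel)) next
    if (spec$habitat_sds[k] > 0) {
      fld <- correlated_field(dm, spec$correlation_length_vox)
      vol[sel] <- spec$habitat_means[k] + spec$habitat_sds[k] * fld[sel]
    } else {
      vol[sel] <- spec$habitat_means[k]
    }
  }
  if (spec$noise_sd > 0)
    vol[inm] <- vol[inm] + stats::rnorm(sum(inm), 0, spec$noise_sd)

  truth <- structure(list(labels = labels, k = K, ch_scores = NULL,
                          dim = dm, spacing_mm = spec$spacing_mm),
                     class = "habitat_map")
  list(volume = image_volume(vol, spec$spacing_mm), mask = mask,
       truth_habitats = truth)
}

#' Cohort specification
#'
#' Describes a multi-center cohort: case counts per center (the default
#' mirrors a 101/43/117/75 four-cohort structure), per-center intensity
#' batch effects, between-case variation of the habitat parameters, and a
#' logistic outcome model on ground-truth habitat summaries whose intercept
#' is calibrated to a target prevalence.
#'
#' Outcome-model coefficients are stated on the z-scale of the ground-truth
#' summaries (features are standardized across the cohort before the linear
#' predictor is formed), so effect sizes are comparable across features.
#' Valid coefficient names are `hab<k>_mean`, `hab<k>_sd` for each habitat,
#' `rim_core_contrast` (outermost minus innermost mean) and `log_volume`.
#'
#' Two batch axes are distinguished: the *center* (which doubles as the
#' cohort split, mirroring a multi-center train/val/test structure) and the
#' *scanner* (the CT machine, drawn per case across all centers), which is
#' the axis carrying the intensity batch effect that ComBat removes. Fitting
#' harmonization on the training cohort is only possible when every batch is
#' represented there, which holds for scanners but not for centers.
#'
#' @param n_cases_per_center integer case counts, one per center (>= 2 each).
#' @param cohort_names cohort split label per center entry.
#' @param center_shift additive intensity offset per center (default 0).
#' @param center_scale multiplicative intensity scale per center (default 1).
#' @param n_scanners scanner count (default 3).
#' @param scanner_shift additive intensity offset per scanner.
#' @param scanner_scale multiplicative intensity scale per scanner.
#' @param outcome_coefficients named log-odds coefficients (z-scale).
#' @param prevalence_target expected positive fraction, in (0,1).
#' @param between_case_mean_sd sd of per-case jitter of habitat means.
#' @param between_case_radius_sd sd (mm) of per-case tumor radius jitter.
#' @param ct_label_shift latent-scale shift linking cT stage to the outcome.
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases_per_center = c(101L, 43L, 117L, 75L),
                        cohort_names = c("train", "val", "test1", "test2"),
                        center_shift = c(0, 0, 0, 0),
                        center_scale = c(1, 1, 1, 1),
                        n_scanners = 3L,
                        scanner_shift = c(0, -15, 20),
                        scanner_scale = c(1, 0.9, 1.1),
                        outcome_coefficients = c(hab2_mean = 1.6,
                                                 hab3_mean = -1.6),
                        prevalence_target = 0.3,
                        between_case_mean_sd = 15,
                        between_case_radius_sd = 1.0,
                        ct_label_shift = 1.2,
                        seed = 1L) {
  n_ctr <- length(n_cases_per_center)
  if (any(n_cases_per_center < 2L)) stop("need >= 2 cases per center")
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence_target must be strictly inside (0,1)")
  if (length(cohort_names) != n_ctr || length(center_shift) != n_ctr ||
      length(center_scale) != n_ctr)
    stop("cohort_names / center_shift / center_scale must match the number of centers")
  if (length(scanner_shift) != n_scanners ||
      length(scanner_scale) != n_scanners)
    stop("scanner_shift / scanner_scale must match n_scanners")
  structure(list(n_cases_per_center = as.integer(n_cases_per_center),
                 cohort_names = cohort_names,
                 center_shift = center_shift, center_scale = center_scale,
                 n_scanners = as.integer(n_scanners),
                 scanner_shift = scanner_shift,
                 scanner_scale = scanner_scale,
                 outcome_coefficients = outcome_coefficients,
                 prevalence_target = prevalence_target,
                 between_case_mean_sd = between_case_mean_sd,
                 between_case_radius_sd = between_case_radius_sd,
                 ct_label_shift = ct_label_shift,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

truth_feature_names <- function(K) {
  c(paste0("hab", seq_len(K), "_mean"), paste0("hab", seq_len(K), "_sd"),
    "rim_core_contrast", "log_volume")
}

#' Generate a synthetic multi-center cohort
#'
#' Draws per-case habitat parameters (means jittered around the phantom
#' spec, radius jittered), computes ground-truth habitat summaries, draws
#' binary outcomes from the logistic model after calibrating the intercept
#' by bisection so the expected prevalence matches the target, draws a
#' clinical table (age, sex, BMI, cT correlated with the outcome, cN), and
#' (optionally) renders each case's volume/mask/habitat map with the
#' per-center intensity batch effect applied.
#'
#' @param cspec a [cohort_spec()].
#' @param pspec a [phantom_spec()] giving the base tumor geometry/texture.
#' @param render logical: render image volumes per case (default TRUE). With
#'   `render = FALSE` only ground-truth summaries and tables are produced,
#'   which is sufficient for feature-level simulation studies.
#' @return list of class `synthetic_cohort`: `cases` (list; volumes NULL
#'   when not rendered), `clinical` (data.frame), `truth` (data.frame of
#'   ground-truth summaries), `calibrated_intercept`.
#' @export
generate_cohort <- function(cspec, pspec, render = TRUE) {
  stopifnot(inherits(cspec, "cohort_spec"), inherits(pspec, "phantom_spec"))
  K <- pspec$n_habitats
  valid <- truth_feature_names(K)
  cf <- cspec$outcome_coefficients
  bad <- setdiff(names(cf), valid)
  if (length(bad) > 0L)
    stop("unresolvable outcome coefficient name(s): ",
         paste(bad, collapse = ", "), "; valid names: ",
         paste(valid, collapse = ", "))
  set.seed(cspec$seed)
  n_ctr <- length(cspec$n_cases_per_center)
  n_tot <- sum(cspec$n_cases_per_center)
  center_id <- rep(paste0("C", seq_len(n_ctr)), cspec$n_cases_per_center)
  cohort <- rep(cspec$cohort_names, cspec$n_cases_per_center)
  case_id <- sprintf("case%04d", seq_len(n_tot))
  scanner_id <- paste0("S", sample.int(cspec$n_scanners, n_tot,
                                       replace = TRUE))

  # per-case habitat parameters
  means <- matrix(rep(pspec$habitat_means, each = n_tot), n_tot, K) +
    matrix(stats::rnorm(n_tot * K, 0, cspec$between_case_mean_sd), n_tot, K)
  sds <- matrix(rep(pspec$habitat_sds, each = n_tot), n_tot, K) *
    exp(matrix(stats::rnorm(n_tot * K, 0, 0.2), n_tot, K))
  radius <- pmax(matrix(rep(pspec$tumor_radius_mm, each = n_tot), n_tot, 3) +
                   stats::rnorm(n_tot, 0, cspec$between_case_radius_sd),
                 2 * max(pspec$spacing_mm))
  half_extent <- (pspec$grid_shape - 1) / 2 * pspec$spacing_mm
  for (a in 1:3) radius[, a] <- pmin(radius[, a], half_extent[a])

  truth <- data.frame(case_id = case_id)
  for (k in seq_len(K)) truth[[paste0("hab", k, "_mean")]] <- means[, k]
  for (k in seq_len(K)) truth[[paste0("hab", k, "_sd")]] <- sds[, k]
  truth$rim_core_contrast <- means[, K] - means[, 1L]
  truth$log_volume <- log(4 / 3 * pi * radius[, 1] * radius[, 2] * radius[, 3])

  # linear predictor on z-scaled truth features, intercept by bisection
  s <- rep(0, n_tot)
  for (nm in names(cf)) {
    x <- truth[[nm]]
    sdx <- stats::sd(x)
    z <- if (sdx > 0) (x - mean(x)) / sdx else rep(0, n_tot)
    s <- s + cf[[nm]] * z
  }
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + s)) -
                         cspec$prevalence_target,
                       interval = c(-30, 30), tol = 1e-10)$root
  p <- stats::plogis(b0 + s)
  label <- stats::rbinom(n_tot, 1L, p)

  clinical <- data.frame(
    case_id = case_id, center = center_id, scanner = scanner_id,
    cohort = cohort, label = label,
    age = round(stats::rnorm(n_tot, 65, 6.5), 1),
    sex = sample(c("F", "M"), n_tot, replace = TRUE, prob = c(0.45, 0.55)),
    bmi = round(stats::rnorm(n_tot, 22.7, 2.4), 1),
    stringsAsFactors = FALSE)
  # cT correlated with outcome via a shifted latent ordinal draw
  lat <- stats::rnorm(n_tot) + cspec$ct_label_shift * label
  cuts <- stats::qnorm(c(0.07, 0.41)) +
    cspec$ct_label_shift * mean(label)  # base probs ~ (0.07, 0.34, 0.59)
  clinical$cT <- paste0("T", findInterval(lat, cuts) + 1L)
  clinical$cN <- paste0("N", sample(0:2, n_tot, replace = TRUE,
                                    prob = c(0.52, 0.36, 0.12)))

  case_seeds <- sample.int(.Machine$integer.max %/% 2L, n_tot)
  cases <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    cs <- list(case_id = case_id[i], center_id = center_id[i],
               scanner_id = scanner_id[i],
               cohort = cohort[i], label = label[i],
               clinical = as.list(clinical[i, c("age", "sex", "bmi",
                                                "cT", "cN")]),
               volume = NULL, mask = NULL, truth_habitats = NULL)
    if (render) {
      psp <- pspec
      psp$habitat_means <- means[i, ]
      psp$habitat_sds <- sds[i, ]
      psp$tumor_radius_mm <- radius[i, ]
      psp$seed <- case_seeds[i]
      ph <- generate_phantom(psp)
      ci <- match(center_id[i], paste0("C", seq_len(n_ctr)))
      si <- match(scanner_id[i], paste0("S", seq_len(cspec$n_scanners)))
      scl <- cspec$center_scale[ci] * cspec$scanner_scale[si]
      sft <- cspec$center_shift[ci] + cspec$scanner_shift[si]
      v <- ph$volume
      v$data[ph$mask$data != 0] <-
        v$data[ph$mask$data != 0] * scl + sft
      cs$volume <- v
      cs$mask <- ph$mask
      cs$truth_habitats <- ph$truth_habitats
    }
    cases[[i]] <- cs
  }
  structure(list(cases = cases, clinical = clinical, truth = truth,
                 calibrated_intercept = b0,
                 cspec = cspec, pspec = pspec),
            class = "synthetic_cohort")
}

#' @exportS3Method print synthetic_cohort
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases, %d centers, prevalence %.3f\n",
              nrow(x$clinical), length(unique(x$clinical$center)),
              mean(x$clinical$label)))
  invisible(x)
}

#' Simulate a second rater's segmentation
#'
#' Perturbs the tumor boundary by thresholding the smoothed mask indicator
#' plus a spatially correlated noise field, emulating inter-rater
#' variability in manual delineation. `boundary_jitter_mm = 0` returns the
#' input unchanged. Deterministic given the seed.
#'
#' @param mask an [roi_mask()], nonempty.
#' @param boundary_jitter_mm boundary perturbation scale in mm (default 1).
#' @param seed integer seed.
#' @param amplitude noise amplitude relative to the indicator step
#'   (default 0.12); larger values lower the Dice overlap.
#' @return the perturbed [roi_mask()].
#' @export
simulate_second_rater <- function(mask, boundary_jitter_mm = 1, seed = 1L,
                                  amplitude = 0.12) {
  if (n_mask_voxels(mask) == 0L) stop("empty mask")
  if (boundary_jitter_mm < 0) stop("boundary_jitter_mm must be >= 0")
  if (boundary_jitter_mm == 0) return(mask)
  set.seed(seed)
  ks <- lapply(1:3, function(ax)
    gaussian_kernel_1d(boundary_jitter_mm / mask$spacing_mm[ax]))
  f <- conv_separable(mask$data + 0, ks)
  eps <- conv_separable(array(stats::rnorm(prod(dim(mask$data))),
                              dim = dim(mask$data)), ks)
  s <- stats::sd(as.vector(eps))
  if (s > 0) eps <- eps / s
  out <- (f + amplitude * eps > 0.5) + 0
  if (sum(out) == 0L)
    stop("jitter emptied the mask; reduce boundary_jitter_mm or amplitude")
  roi_mask(out, mask$spacing_mm, mask$origin_mm)
}

#' Dice overlap of two masks
#'
#' @param a,b [roi_mask()]s with identical geometry.
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(a, b) {
  stopifnot_same_geometry(a, b)
  2 * sum(a$data != 0 & b$data != 0) / (sum(a$data != 0) + sum(b$data != 0))
}

#' Write a rendered cohort to disk
#'
#' Volumes, masks and planted habitat maps as NIfTI, the clinical table as
#' CSV, and a JSON manifest mapping case ids to files, center, cohort and
#' label.
#'
#' @param cohort a rendered [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (cs in cohort$cases) {
    if (is.null(cs$volume)) stop("cohort was generated with render = FALSE")
    vp <- file.path(dir, paste0(cs$case_id, "_image.nii.gz"))
    mp <- file.path(dir, paste0(cs$case_id, "_mask.nii.gz"))
    hp <- file.path(dir, paste0(cs$case_id, "_habitats.nii.gz"))
    write_volume(cs$volume, vp)
    write_mask(cs$mask, mp)
    write_volume(image_volume(cs$truth_habitats$labels + 0,
                              cs$volume$spacing_mm), hp)
    manifest[[cs$case_id]] <- list(image = vp, mask = mp, habitats = hp,
                                   center = cs$center_id, cohort = cs$cohort,
                                   label = cs$label)
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  mpth <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpth, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpth)
}
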