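# Feature-level ComBat harmonization with a fit/apply split so the model can
# be estimated on the training cohort and applied frozen to held-out cases.

#' Identify feature columns of a feature table
#'
#' Feature tables carry one row per case: identifier/metadata columns
#' (`case_id`, `center`, `cohort`, `label` and any non-numeric column) plus
#' named numeric feature columns.
#'
#' @param table a data.frame feature table.
#' @param exclude further column names to treat as metadata.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table, exclude = character()) {
  meta <- c("case_id", "center", "cohort", "label", exclude)
  nm <- setdiff(names(table), meta)
  nm[vapply(table[nm], is.numeric, logical(1L))]
}

#' ComBat batch-effect harmonization of a radiomic feature table
#'
#' Location/scale ComBat: each feature is standardized against its grand mean
#' and pooled variance, per-batch location (gamma) and scale (delta^2)
#' parameters are estimated, optionally shrunk by the parametric
#' empirical-Bayes step (normal prior on gamma, inverse-gamma on delta^2),
#' and removed. `combat_harmonize` fits on the rows it is given and returns
#' the harmonized table plus the fitted model; `combat_apply` applies a
#' frozen model to new cases from batches seen at fit time.
#'
#' @param table data.frame feature table (see [feature_columns()]).
#' @param batch_col name of the column holding the batch/center id.
#' @param eb logical; apply parametric empirical-Bayes shrinkage (default
#'   TRUE). With `eb = FALSE` the per-batch moments are removed exactly.
#' @param features optional character vector restricting the harmonized
#'   columns.
#' @return `combat_harmonize`: list with `table` (harmonized) and `model`
#'   (class `combat_model`). `combat_apply`: the harmonized table.
#' @export
combat_harmonize <- function(table, batch_col = "center", eb = TRUE,
                             features = NULL) {
  if (!batch_col %in% names(table)) stop("unknown batch column: ", batch_col)
  feats <- if (is.null(features)) feature_columns(table, exclude = batch_col) else features
  if (length(feats) == 0L) stop("no numeric feature columns to harmonize")
  batch <- as.character(table[[batch_col]])
  tab <- table(batch)
  if (length(tab) < 2L) {
    warning("single batch: ComBat reduces to the identity transform")
    model <- structure(list(identity = TRUE, batch_col = batch_col,
                            features = feats), class = "combat_model")
    return(list(table = table, model = model))
  }
  if (any(tab < 2L))
    stop("each batch needs >= 2 cases; too small: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  X <- as.matrix(table[feats])
  if (any(!is.finite(X))) stop("feature table contains non-finite values")

  batches <- names(tab)
  n <- nrow(X)
  n_b <- as.integer(tab[batches])
  idx_b <- lapply(batches, function(b) which(batch == b))

  batch_means <- t(matrix(vapply(idx_b,
                                 function(ii) colMeans(X[ii, , drop = FALSE]),
                                 numeric(length(feats))),
                          nrow = length(feats)))
  grand_mean <- colSums(batch_means * (n_b / n))
  resid <- X - batch_means[match(batch, batches), , drop = FALSE]
  var_pooled <- colSums(resid^2) / n
  var_pooled[var_pooled <= 0] <- 1e-12

  Z <- sweep(sweep(X, 2L, grand_mean, "-"), 2L, sqrt(var_pooled), "/")
  gamma_hat <- t(matrix(vapply(idx_b,
                               function(ii) colMeans(Z[ii, , drop = FALSE]),
                               numeric(length(feats))),
                        nrow = length(feats)))
  delta_hat <- t(matrix(vapply(idx_b, function(ii) {
    apply(Z[ii, , drop = FALSE], 2L, stats::var)
  }, numeric(length(feats))), nrow = length(feats)))
  delta_hat[delta_hat <= 0] <- 1e-12

  if (eb) {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (bi in seq_along(batches)) {
      sol <- combat_eb_solve(Z[idx_b[[bi]], , drop = FALSE],
                             gamma_hat[bi, ], delta_hat[bi, ])
      gamma_star[bi, ] <- sol$gamma
      delta_star[bi, ] <- sol$delta2
    }
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }

  model <- structure(list(
    identity = FALSE, batch_col = batch_col, features = feats,
    batches = batches, grand_mean = grand_mean, var_pooled = var_pooled,
    gamma_star = gamma_star, delta_star = delta_star, eb = eb
  ), class = "combat_model")

  list(table = combat_apply(model, table), model = model)
}

# Parametric EB estimates for one batch: iterate the conditional posterior
# means of gamma (normal prior) and delta^2 (inverse-gamma prior).
combat_eb_solve <- function(Zb, g_hat, d_hat, tol = 1e-6, max_iter = 200L) {
  n_i <- nrow(Zb)
  g_bar <- mean(g_hat)
  t2 <- stats::var(g_hat)
  if (!is.finite(t2) || t2 <= 0) t2 <- 1e-12
  m <- mean(d_hat); s2 <- stats::var(d_hat)
  if (!is.finite(s2) || s2 <= 0) s2 <- 1e-12
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_new <- g_hat
  d_new <- d_hat
  for (it in seq_len(max_iter)) {
    g_old <- g_new; d_old <- d_new
    g_new <- (n_i * t2 * g_hat + d_new * g_bar) / (n_i * t2 + d_new)
    sum2 <- colSums((Zb - matrix(g_new, n_i, length(g_new), byrow = TRUE))^2)
    d_new <- (0.5 * sum2 + b_prior) / (n_i / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                  abs(d_new - d_old) / (abs(d_old) + 1e-12))
    if (change < tol) break
  }
  list(gamma = g_new, delta2 = d_new)
}

#' @rdname combat_harmonize
#' @param model a fitted `combat_model`.
#' @export
combat_apply <- function(model, table) {
  stopifnot(inherits(model, "combat_model"))
  if (isTRUE(model$identity)) return(table)
  batch <- as.character(table[[model$batch_col]])
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen) > 0L)
    stop("batch not seen at fit time: ", paste(unseen, collapse = ", "))
  X <- as.matrix(table[model$features])
  Z <- sweep(sweep(X, 2L, model$grand_mean, "-"), 2L, sqrt(model$var_pooled), "/")
  bi <- match(batch, model$batches)
  Zadj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  Xadj <- sweep(sweep(Zadj, 2L, sqrt(model$var_pooled), "*"), 2L,
                model$grand_mean, "+")
  out <- table
  out[model$features] <- as.data.frame(Xadj)
  out
}

#' Inter-rater feature reliability gate (ICC(2,1))
#'
#' Computes, per feature, the two-way random-effects, absolute-agreement,
#' single-rater intraclass correlation between the feature values obtained
#' from two raters' segmentations, and retains features whose ICC meets the
#' threshold. Absolute agreement penalizes systematic offsets between raters,
#' so a constant bias yields ICC < 1.
#'
#' @param features_rater1,features_rater2 feature tables with identical
#'   `case_id` sets and feature columns.
#' @param threshold retention threshold (default 0.85).
#' @return character vector of retained feature names; the per-feature ICC
#'   values are attached as attribute `"icc"`.
#' @export
case_icc_gate <- function(features_rater1, features_rater2, threshold = 0.85) {
  f1 <- features_rater1; f2 <- features_rater2
  if (!"case_id" %in% names(f1) || !"case_id" %in% names(f2))
    stop("feature tables need a case_id column")
  f2 <- f2[match(f1$case_id, f2$case_id), , drop = FALSE]
  if (any(is.na(f2$case_id)) || !identical(as.character(f1$case_id),
                                           as.character(f2$case_id)))
    stop("case sets differ between raters")
  feats <- intersect(feature_columns(f1), feature_columns(f2))
  if (length(feats) == 0L) stop("no shared feature columns")
  if (nrow(f1) < 3L) stop("ICC requires at least 3 cases")
  icc <- vapply(feats, function(nm) icc_21(f1[[nm]], f2[[nm]]), numeric(1L))
  retained <- feats[!is.na(icc) & icc >= threshold]
  attr(retained, "icc") <- icc
  retained
}

#' Two-way random absolute-agreement single-rater ICC
#'
#' @param x1,x2 numeric vectors: the same cases measured by two raters.
#' @return ICC(2,1) as a single number.
#' @export
icc_21 <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  n <- length(x1); k <- 2
  X <- cbind(x1, x2)
  G <- mean(X)
  Ri <- rowMeans(X); Cj <- colMeans(X)
  MSR <- k * sum((Ri - G)^2) / (n - 1)
  MSC <- n * sum((Cj - G)^2) / (k - 1)
  MSE <- sum((X - outer(Ri, rep(1, k)) -
                matrix(Cj, n, k, byrow = TRUE) + G)^2) / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (denom <= 0) return(NA_real_)
  (MSR - MSE) / denom
}
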