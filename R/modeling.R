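# Feature standardization, cross-validated LASSO selection, nested CV and
# classifier training. All fitting is split-aware: statistics, selection and
# hyperparameters come from the training rows only.

#' Standardize features on training statistics
#'
#' Z-scores every feature column using mean and population standard
#' deviation computed from the training split only, applied identically to
#' all splits (anti-leakage). Zero-sd features are dropped with a warning.
#'
#' @param table data.frame feature table with a `cohort` column.
#' @param fit_split split whose rows provide the statistics (default
#'   `"train"`).
#' @param features optional restriction of the columns to standardize.
#' @return list with `table` (standardized, dropped columns removed) and
#'   `stats` (data.frame `feature`, `mean`, `sd`).
#' @export
standardize_features <- function(table, fit_split = "train", features = NULL) {
  feats <- if (is.null(features)) feature_columns(table) else features
  tr <- table$cohort == fit_split
  if (!any(tr)) stop("training split is empty")
  mu <- vapply(feats, function(f) mean(table[[f]][tr]), numeric(1L))
  sdv <- vapply(feats, function(f) {
    x <- table[[f]][tr]
    sqrt(mean((x - mean(x))^2))
  }, numeric(1L))
  drop <- feats[sdv == 0 | !is.finite(sdv)]
  if (length(drop) > 0L) {
    if (length(drop) == length(feats))
      stop("all features have zero training-split standard deviation")
    warning("dropping zero-variance feature(s): ",
            paste(utils::head(drop, 5L), collapse = ", "),
            if (length(drop) > 5L) ", ...")
    table <- table[setdiff(names(table), drop)]
    keep <- !(feats %in% drop)
    feats <- feats[keep]; mu <- mu[keep]; sdv <- sdv[keep]
  }
  for (i in seq_along(feats))
    table[[feats[i]]] <- (table[[feats[i]]] - mu[i]) / sdv[i]
  list(table = table,
       stats = data.frame(feature = feats, mean = unname(mu),
                          sd = unname(sdv), stringsAsFactors = FALSE))
}

# Stratified fold assignment, deterministic given the seed.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated LASSO feature selection
#'
#' L1-penalized regression over a log-spaced lambda path with stratified
#' k-fold cross-validation; the optimal lambda minimizes the mean CV loss
#' and the selected set is the features with nonzero coefficients there.
#' The default objective is penalized logistic regression (binomial
#' deviance CV); `mode = "mse"` instead fits squared-error loss on the 0/1
#' labels, the criterion sometimes quoted for radiomic signatures.
#'
#' @param table data.frame with a `label` column and feature columns
#'   (typically the standardized training split).
#' @param folds CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param mode `"binomial"` (default) or `"mse"`.
#' @param features optional feature subset.
#' @return object of class `lasso_result`: `lambda`, `coefficients`
#'   (features x lambda matrix), `cv_mean`, `cv_sd`, `lambda_opt`,
#'   `selected`, `n_selected`, `mode`.
#' @export
lasso_select <- function(table, folds = 10L, seed = 1L,
                         mode = c("binomial", "mse"), features = NULL) {
  mode <- match.arg(mode)
  feats <- if (is.null(features)) feature_columns(table) else features
  y <- as.integer(table$label)
  if (any(is.na(y))) stop("labels required for all rows")
  if (sum(y == 1L) < folds || sum(y == 0L) < folds)
    stop("need at least `folds` cases of each class for stratified folds")
  X <- as.matrix(table[feats])
  foldid <- stratified_folds(y, folds, seed)
  fam <- if (mode == "binomial") "binomial" else "gaussian"
  meas <- if (mode == "binomial") "deviance" else "mse"
  set.seed(seed)
  cv <- glmnet::cv.glmnet(X, y, family = fam, alpha = 1, foldid = foldid,
                          type.measure = meas, standardize = FALSE)
  fit <- cv$glmnet.fit
  co <- as.matrix(fit$beta)
  lam_opt <- cv$lambda.min
  idx_opt <- which.min(abs(cv$lambda - lam_opt))
  sel <- rownames(co)[co[, idx_opt] != 0]
  structure(list(lambda = cv$lambda, coefficients = co,
                 cv_mean = cv$cvm, cv_sd = cv$cvsd,
                 lambda_opt = lam_opt, selected = sel,
                 n_selected = length(sel), mode = mode,
                 a0_opt = as.numeric(fit$a0[idx_opt]),
                 beta_opt = co[, idx_opt], features = feats),
            class = "lasso_result")
}

#' Penalized logistic signature from a LASSO fit
#'
#' Wraps the penalized coefficients at the optimal lambda as a
#' `trained_model`, the conventional radiomic-signature construction: the
#' score is the shrunk linear predictor passed through the logistic
#' function, so probabilities stay calibrated rather than saturating the
#' way an unpenalized refit on selected features can.
#'
#' @param lr a [lasso_select()] result (binomial mode).
#' @param table the training rows the LASSO was fit on (sets the Youden
#'   threshold).
#' @return a `trained_model` (algorithm `"logistic"`).
#' @export
lasso_signature_model <- function(lr, table) {
  stopifnot(inherits(lr, "lasso_result"))
  if (lr$mode != "binomial")
    stop("signature model requires a binomial-mode LASSO fit")
  feats <- lr$features
  mdl <- structure(list(
    algorithm = "logistic",
    fit = structure(list(beta = c(lr$a0_opt, lr$beta_opt)),
                    class = "ridge_logistic"),
    hyperparameters = list(lambda = lr$lambda_opt),
    features = feats,
    center = stats::setNames(rep(0, length(feats)), feats),
    scale = stats::setNames(rep(1, length(feats)), feats),
    threshold = NA_real_, seed = NA_integer_, train_auc = NA_real_),
    class = "trained_model")
  p <- predict(mdl, table)
  mdl$threshold <- youden_threshold(p, as.integer(table$label))
  mdl$train_auc <- auc_midrank(p, as.integer(table$label))
  mdl
}

#' @exportS3Method print lasso_result
print.lasso_result <- function(x, ...) {
  cat(sprintf("<lasso_result> %d features selected at lambda = %.4g (%s CV)\n",
              x$n_selected, x$lambda_opt, x$mode))
  invisible(x)
}

#' Train a classifier with exhaustive grid search
#'
#' Stratified cross-validated grid search (selection metric: pooled CV AUC),
#' refit of the best configuration on all supplied rows, and a Youden
#' decision threshold frozen on the training predictions. Standardization
#' statistics are estimated from the supplied rows and stored in the model,
#' so prediction on raw held-out rows applies the training transform.
#'
#' @param table training rows: data.frame with `label` and feature columns.
#' @param algorithm one of `"logistic"`, `"svm"`, `"random_forest"`,
#'   `"extra_trees"`, `"gradient_boosting"`.
#' @param features feature subset to train on (default: all feature
#'   columns).
#' @param grid data.frame of hyperparameter combinations; `NULL` uses the
#'   per-algorithm default (SVM kernels linear/polynomial/radial; tree depth
#'   1-5; boosting iterations up to 100).
#' @param folds CV folds for the grid search (default 5).
#' @param seed integer seed.
#' @return object of class `trained_model` with a [predict()] method
#'   returning probabilities.
#' @export
fit_classifier <- function(table, algorithm = c("logistic", "svm",
                                                "random_forest",
                                                "extra_trees",
                                                "gradient_boosting"),
                           features = NULL, grid = NULL, folds = 5L,
                           seed = 1L) {
  algorithm <- tryCatch(match.arg(algorithm),
                        error = function(e)
                          stop("unknown algorithm; supported: logistic, svm, ",
                               "random_forest, extra_trees, gradient_boosting",
                               call. = FALSE))
  feats <- if (is.null(features)) feature_columns(table) else features
  if (length(feats) == 0L) stop("no features to train on")
  y <- as.integer(table$label)
  X <- as.matrix(table[feats])
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu, "-")^2))
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
  if (is.null(grid)) grid <- default_grid(algorithm)

  best <- NULL
  if (nrow(grid) > 1L) {
    foldid <- stratified_folds(y, folds, seed)
    cv_auc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      pred <- rep(NA_real_, length(y))
      for (f in seq_len(folds)) {
        tr <- foldid != f
        fit <- fit_algorithm(algorithm, Xs[tr, , drop = FALSE], y[tr],
                             grid[g, , drop = FALSE], seed)
        pred[!tr] <- predict_algorithm(algorithm, fit,
                                       Xs[!tr, , drop = FALSE])
      }
      cv_auc[g] <- auc_midrank(pred, y)
    }
    best <- grid[which.max(cv_auc), , drop = FALSE]
    attr(best, "cv_auc") <- max(cv_auc)
  } else {
    best <- grid[1L, , drop = FALSE]
  }
  fit <- fit_algorithm(algorithm, Xs, y, best, seed)
  train_prob <- predict_algorithm(algorithm, fit, Xs)
  thr <- youden_threshold(train_prob, y)
  structure(list(algorithm = algorithm, fit = fit,
                 hyperparameters = as.list(best),
                 features = feats, center = mu, scale = sdv,
                 threshold = thr, seed = seed,
                 train_auc = auc_midrank(train_prob, y)),
            class = "trained_model")
}

default_grid <- function(algorithm) {
  switch(algorithm,
    logistic = data.frame(dummy = 1),
    svm = expand.grid(kernel = c("linear", "polynomial", "radial"),
                      cost = 1, stringsAsFactors = FALSE),
    random_forest = expand.grid(max_depth = 1:5, num_trees = 300L),
    extra_trees = expand.grid(max_depth = 1:5, num_trees = 300L),
    gradient_boosting = expand.grid(max_depth = 1:5,
                                    nrounds = c(10L, 50L, 100L)))
}

fit_algorithm <- function(algorithm, X, y, par, seed) {
  set.seed(seed)
  df <- as.data.frame(X)
  switch(algorithm,
    logistic = suppressWarnings(
      stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial())),
    svm = e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                     kernel = par$kernel, cost = par$cost,
                     probability = TRUE),
    random_forest = ranger::ranger(
      x = df, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = par$num_trees, max.depth = par$max_depth,
      seed = seed, num.threads = 1L),
    extra_trees = ranger::ranger(
      x = df, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = par$num_trees, max.depth = par$max_depth,
      splitrule = "extratrees", seed = seed, num.threads = 1L),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = par$max_depth,
                    eta = 0.1, nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
      nrounds = par$nrounds, verbose = 0))
}

predict_algorithm <- function(algorithm, fit, X) {
  switch(algorithm,
    logistic = {
      if (inherits(fit, "ridge_logistic"))
        return(as.numeric(stats::plogis(fit$beta[1L] + X %*% fit$beta[-1L])))
      p <- stats::predict(fit, newdata = as.data.frame(X), type = "response")
      as.numeric(p)
    },
    svm = {
      pr <- stats::predict(fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    random_forest = ,
    extra_trees = stats::predict(fit, data = as.data.frame(X),
                                 num.threads = 1L)$predictions[, "1"],
    gradient_boosting = as.numeric(stats::predict(
      fit, xgboost::xgb.DMatrix(X, nthread = 1L))))
}

#' Predict probabilities from a trained model
#'
#' Refuses feature tables whose columns do not cover the model's schema.
#'
#' @param object a `trained_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return numeric probabilities in [0, 1].
#' @export
predict.trained_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0L)
    stop("newdata lacks model feature(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  X <- as.matrix(newdata[object$features])
  Xs <- sweep(sweep(X, 2L, object$center, "-"), 2L, object$scale, "/")
  predict_algorithm(object$algorithm, object$fit, Xs)
}

#' @exportS3Method print trained_model
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s on %d features, threshold %.3f, train AUC %.3f\n",
              x$algorithm, length(x$features), x$threshold, x$train_auc))
  invisible(x)
}

#' Nested cross-validation with in-fold feature selection
#'
#' In every outer fold, standardization statistics, the LASSO-selected
#' feature set and any hyperparameter search are computed on the outer
#' training part only; the held-out predictions are pooled into an unbiased
#' CV AUC. `naive = TRUE` instead selects features once on all rows before
#' the outer loop -- the leaky variant, retained only to demonstrate the
#' optimism that nesting removes.
#'
#' @param table data.frame with `label` and feature columns.
#' @param algorithm classifier refit on the selected features per fold, or
#'   `"lasso"` to use the penalized fit itself as the per-fold model (see
#'   [lasso_signature_model()]).
#' @param outer_folds,inner_folds fold counts (defaults 5 and 10).
#' @param seed integer seed.
#' @param mode LASSO objective, see [lasso_select()].
#' @param naive run selection on all rows first (leaky; default FALSE).
#' @return list with `auc`, `predictions` (data.frame `row`, `fold`,
#'   `prob`, `label`), `n_selected` per fold.
#' @export
nested_cross_validate <- function(table, algorithm = "logistic",
                                  outer_folds = 5L, inner_folds = 10L,
                                  seed = 1L, mode = "binomial",
                                  naive = FALSE) {
  y <- as.integer(table$label)
  feats <- feature_columns(table)
  fold <- stratified_folds(y, outer_folds, seed)
  prob <- rep(NA_real_, length(y))
  nsel <- integer(outer_folds)
  sel_all <- NULL
  if (naive) {
    tab_all <- table
    tab_all$cohort <- "train"
    st <- standardize_features(tab_all, features = feats)
    sel_all <- lasso_select(st$table, folds = inner_folds, seed = seed,
                            mode = mode)$selected
  }
  for (f in seq_len(outer_folds)) {
    tr_rows <- fold != f
    tab <- table
    tab$cohort <- ifelse(tr_rows, "train", "heldout")
    st <- suppressWarnings(standardize_features(tab, features = feats))
    tr_tab <- st$table[tr_rows, , drop = FALSE]
    te_tab <- st$table[!tr_rows, , drop = FALSE]
    if (algorithm == "lasso" && !naive) {
      lr <- lasso_select(tr_tab, folds = inner_folds, seed = seed + f,
                         mode = mode)
      nsel[f] <- lr$n_selected
      mdl <- lasso_signature_model(lr, tr_tab)
      prob[!tr_rows] <- predict(mdl, te_tab)
      next
    }
    sel <- if (naive) intersect(sel_all, feature_columns(tr_tab))
           else lasso_select(tr_tab, folds = inner_folds,
                             seed = seed + f, mode = mode)$selected
    nsel[f] <- length(sel)
    if (length(sel) == 0L) {
      prob[!tr_rows] <- mean(tr_tab$label)
    } else {
      refit <- if (algorithm == "lasso") "logistic" else algorithm
      mdl <- fit_classifier(tr_tab, algorithm = refit, features = sel,
                            seed = seed + f)
      prob[!tr_rows] <- suppressWarnings(predict(mdl, te_tab))
    }
  }
  list(auc = auc_midrank(prob, y),
       predictions = data.frame(row = seq_along(y), fold = fold,
                                prob = prob, label = y),
       n_selected = nsel)
}

#' Univariable, multivariable and combined logistic signatures
#'
#' Reproduces the clinical-modeling layer: (a) one univariable logistic fit
#' per clinical covariate with odds ratios and Wald 95% CIs; (b) a
#' multivariable fit on the covariates univariably significant at p < 0.05;
#' (c) the combined signature, a logistic model on cT stage (ordinal 1/2/3)
#' plus the radiomics and habitat scores (each model's predicted
#' probability). Complete separation is flagged and refit with a small
#' ridge penalty.
#'
#' @param clinical data.frame with `label` and clinical covariate columns
#'   (`age`, `sex`, `bmi`, `cT`, `cN` or any numeric/factor subset).
#' @param covariates covariate names for the univariable scan.
#' @param scores optional data.frame with columns `radiomics_score` and
#'   `habitat_score` aligned to `clinical` rows for the combined model.
#' @param alpha univariable inclusion threshold (default 0.05).
#' @return list with `univariable` (data.frame), `multivariable`
#'   (data.frame or NULL), `combined` (a `trained_model` or NULL).
#' @export
fit_logistic_signatures <- function(clinical,
                                    covariates = c("age", "sex", "bmi",
                                                   "cT", "cN"),
                                    scores = NULL, alpha = 0.05) {
  covariates <- intersect(covariates, names(clinical))
  enc <- encode_clinical(clinical, covariates)
  missing_rows <- which(!stats::complete.cases(enc))
  if (length(missing_rows) > 0L)
    stop("incomplete covariates for case(s): ",
         paste(utils::head(missing_rows, 5L), collapse = ", "))
  y <- as.integer(clinical$label)

  uni <- do.call(rbind, lapply(covariates, function(cv) {
    fit <- suppressWarnings(stats::glm(y ~ enc[[cv]],
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients
    if (nrow(co) < 2L)
      return(data.frame(covariate = cv, odds_ratio = NA, ci_low = NA,
                        ci_high = NA, p_value = NA))
    b <- co[2L, 1L]; se <- co[2L, 2L]; p <- co[2L, 4L]
    data.frame(covariate = cv, odds_ratio = exp(b),
               ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
               p_value = p, stringsAsFactors = FALSE)
  }))

  keep <- uni$covariate[!is.na(uni$p_value) & uni$p_value < alpha]
  multi <- NULL
  if (length(keep) > 0L) {
    dfm <- cbind(data.frame(y = y), enc[keep])
    fit <- suppressWarnings(stats::glm(y ~ ., data = dfm,
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients
    multi <- data.frame(covariate = rownames(co)[-1L],
                        odds_ratio = exp(co[-1L, 1L]),
                        ci_low = exp(co[-1L, 1L] - 1.96 * co[-1L, 2L]),
                        ci_high = exp(co[-1L, 1L] + 1.96 * co[-1L, 2L]),
                        p_value = co[-1L, 4L], stringsAsFactors = FALSE,
                        row.names = NULL)
  }

  combined <- NULL
  if (!is.null(scores)) {
    tab <- data.frame(cT = enc$cT,
                      radiomics_score = scores$radiomics_score,
                      habitat_score = scores$habitat_score,
                      label = y)
    combined <- fit_logistic_ridge_fallback(tab, c("cT", "radiomics_score",
                                                   "habitat_score"))
  }
  list(univariable = uni, multivariable = multi, combined = combined)
}

# Ordinal/indicator encoding of clinical covariates: cT/cN map to 1/2/3 and
# 0/1/2, sex to 0/1; numeric columns pass through.
encode_clinical <- function(clinical, covariates) {
  out <- list()
  for (cv in covariates) {
    x <- clinical[[cv]]
    out[[cv]] <- if (cv == "cT") as.numeric(factor(x, levels = c("T1", "T2", "T3")))
    else if (cv == "cN") as.numeric(factor(x, levels = c("N0", "N1", "N2"))) - 1
    else if (cv == "sex") as.numeric(x == "M")
    else as.numeric(x)
  }
  as.data.frame(out)
}

# Logistic fit that detects complete separation (divergent coefficients)
# and falls back to a lightly ridge-penalized fit with a warning.
fit_logistic_ridge_fallback <- function(table, features) {
  mdl <- fit_classifier(table, algorithm = "logistic", features = features)
  co <- stats::coef(mdl$fit)
  if (any(!is.finite(co)) || any(abs(co[-1L]) > 15)) {
    warning("possible complete separation; refitting with ridge penalty")
    X <- as.matrix(table[features])
    Xs <- sweep(sweep(X, 2L, mdl$center, "-"), 2L, mdl$scale, "/")
    y <- as.integer(table$label)
    rf <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                         lambda = 1e-2, standardize = FALSE)
    beta <- as.numeric(stats::coef(rf))
    mdl$fit <- structure(list(beta = beta), class = "ridge_logistic")
    mdl$threshold <- youden_threshold(
      as.numeric(stats::plogis(beta[1L] + Xs %*% beta[-1L])), y)
  }
  mdl
}
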