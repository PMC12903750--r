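# Feature-level simulation of the four-signature study and the multi-cohort
# comparison report. The generative model plants outcome signal exclusively
# in habitat-level summaries; whole-tumor radiomics only sees volume-mixed
# aggregates of the same quantities, and the clinical block carries a weak
# cT association -- the structural analogue of the comparison the habitat
# approach is designed to win.

#' Simulate a measured feature table for the four-signature study
#'
#' Builds on [generate_cohort()] (`render = FALSE`): ground-truth habitat
#' summaries are drawn per case, the binary outcome comes from the logistic
#' model on (z-scaled) truth features, and measured features are the truth
#' plus measurement noise. Habitat features are the per-habitat summaries
#' (`hab<k>_mean`, `hab<k>_sd`, `rim_core_contrast`) plus uninformative
#' noise columns; whole-tumor radiomics features are volume-weighted
#' aggregates of the same habitat parameters (mean, pooled sd, log volume)
#' plus their own noise columns, so their signal is attenuated by mixing.
#' Per-scanner additive shifts are applied to every measured imaging feature
#' (batch effect), to be removed by ComBat inside [run_study()].
#'
#' @param seed integer seed.
#' @param cspec a [cohort_spec()]; the default mirrors the 101/43/117/75
#'   four-cohort structure.
#' @param pspec a [phantom_spec()] for the habitat parameters.
#' @param measurement_sd sd of measurement noise added to true summaries.
#' @param n_noise_habitat,n_noise_radiomics uninformative feature counts.
#' @param batch_sd per-center feature-shift scale (in feature-sd units).
#' @return list with `table` (data.frame: case_id, center, cohort, label,
#'   clinical columns, then feature columns), `habitat_features`,
#'   `radiomics_features`, `clinical_covariates` (name vectors), `truth`,
#'   `calibrated_intercept`.
#' @export
simulate_signature_cohort <- function(seed = 1L,
                                      cspec = cohort_spec(seed = seed),
                                      pspec = phantom_spec(seed = seed),
                                      measurement_sd = 5,
                                      n_noise_habitat = 20L,
                                      n_noise_radiomics = 20L,
                                      batch_sd = 0.6) {
  coh <- generate_cohort(cspec, pspec, render = FALSE)
  tr <- coh$truth
  n <- nrow(tr)
  K <- pspec$n_habitats
  set.seed(seed + 7L)

  feats <- list()
  for (k in seq_len(K)) {
    feats[[paste0("hab", k, "_mean")]] <-
      tr[[paste0("hab", k, "_mean")]] + stats::rnorm(n, 0, measurement_sd)
    feats[[paste0("hab", k, "_sd")]] <-
      tr[[paste0("hab", k, "_sd")]] + stats::rnorm(n, 0, measurement_sd / 3)
  }
  feats$rim_core_contrast <-
    feats[[paste0("hab", K, "_mean")]] - feats$hab1_mean
  for (j in seq_len(n_noise_habitat))
    feats[[sprintf("hab_noise_%02d", j)]] <- stats::rnorm(n)
  hab_names <- names(feats)

  mean_mat <- vapply(seq_len(K), function(k) tr[[paste0("hab", k, "_mean")]],
                     numeric(n))
  sd_mat <- vapply(seq_len(K), function(k) tr[[paste0("hab", k, "_sd")]],
                   numeric(n))
  whole_mean <- rowMeans(mean_mat)
  whole_sd <- sqrt(rowMeans(sd_mat^2) +
                     apply(mean_mat, 1L, stats::var) * (K - 1) / K)
  rad <- list(
    whole_mean = whole_mean + stats::rnorm(n, 0, measurement_sd),
    whole_sd = whole_sd + stats::rnorm(n, 0, measurement_sd),
    whole_energy = whole_mean^2 + whole_sd^2 +
      stats::rnorm(n, 0, stats::sd(whole_mean^2 + whole_sd^2) * 0.2),
    log_volume = tr$log_volume + stats::rnorm(n, 0, 0.1))
  for (j in seq_len(n_noise_radiomics))
    rad[[sprintf("rad_noise_%02d", j)]] <- stats::rnorm(n)
  rad_names <- names(rad)

  table <- cbind(coh$clinical, as.data.frame(feats), as.data.frame(rad))

  # per-scanner additive batch shifts on every measured imaging feature
  scanners <- sort(unique(table$scanner))
  img_feats <- c(hab_names, rad_names)
  shifts <- matrix(stats::rnorm(length(scanners) * length(img_feats), 0,
                                batch_sd),
                   length(scanners), length(img_feats),
                   dimnames = list(scanners, img_feats))
  for (f in img_feats) {
    s <- stats::sd(table[[f]])
    table[[f]] <- table[[f]] + shifts[table$scanner, f] * s
  }

  list(table = table, habitat_features = hab_names,
       radiomics_features = rad_names,
       clinical_covariates = c("age", "sex", "bmi", "cT", "cN"),
       truth = tr, calibrated_intercept = coh$calibrated_intercept)
}

#' Run the four-signature study on a simulated cohort
#'
#' The full comparison pipeline at the feature-table level: ComBat
#' harmonization fitted on the training cohort and applied frozen to every
#' split, training-split standardization, LASSO selection and classifier
#' fitting per imaging signature, a clinical logistic signature, and the
#' combined logistic model on cT plus the radiomics and habitat scores
#' (each component model's predicted probability). Evaluation covers every
#' cohort: ROC/AUC with DeLong CIs, pairwise DeLong matrices, confusion
#' metrics at the training-frozen Youden threshold, Hosmer-Lemeshow
#' calibration and decision curves.
#'
#' @param seed integer seed driving cohort simulation and every fit.
#' @param sim optional pre-built [simulate_signature_cohort()] result.
#' @param algorithm model for the imaging signatures: `"lasso"` (default,
#'   the penalized signature itself) or any [fit_classifier()] algorithm
#'   refit on the LASSO-selected features.
#' @param lasso_folds folds for LASSO selection (default 10).
#' @param combat apply ComBat harmonization (default TRUE).
#' @return a `study_report`, see [assemble_report()].
#' @export
run_study <- function(seed = 1L, sim = NULL, algorithm = "lasso",
                      lasso_folds = 10L, combat = TRUE) {
  if (is.null(sim)) sim <- simulate_signature_cohort(seed)
  tab <- sim$table
  img_feats <- c(sim$habitat_features, sim$radiomics_features)

  if (combat) {
    cb <- combat_harmonize(tab[tab$cohort == "train", , drop = FALSE],
                           batch_col = "scanner", features = img_feats)
    tab_h <- combat_apply(cb$model, tab)
  } else {
    tab_h <- tab
    cb <- NULL
  }

  enc <- encode_clinical(tab_h, c("age", "sex", "bmi", "cT", "cN"))
  names(enc) <- paste0("clin_", names(enc))
  tab_h <- cbind(tab_h, enc)
  clin_feats <- names(enc)

  train <- tab_h[tab_h$cohort == "train", , drop = FALSE]

  fit_signature <- function(feats, use_lasso = TRUE, algo = algorithm,
                            seed_off = 0L) {
    st <- suppressWarnings(standardize_features(tab_h, features = feats))
    tr <- st$table[st$table$cohort == "train", , drop = FALSE]
    feats_kept <- intersect(feats, names(st$table))
    if (use_lasso && algo == "lasso") {
      lr <- lasso_select(tr, folds = lasso_folds, seed = seed + seed_off,
                         features = feats_kept)
      return(list(model = lasso_signature_model(lr, tr), table = st$table,
                  selected = lr$selected))
    }
    sel <- if (use_lasso)
      lasso_select(tr, folds = lasso_folds, seed = seed + seed_off,
                   features = feats_kept)$selected
    else feats_kept
    if (length(sel) == 0L) sel <- feats_kept  # fall back to the full set
    mdl <- fit_classifier(tr, algorithm = algo, features = sel,
                          seed = seed + seed_off)
    list(model = mdl, table = st$table, selected = sel)
  }

  sig_hab <- fit_signature(sim$habitat_features, TRUE, seed_off = 11L)
  sig_rad <- fit_signature(sim$radiomics_features, TRUE, seed_off = 22L)
  sig_cli <- fit_signature(clin_feats, FALSE, algo = "logistic",
                           seed_off = 33L)

  prob_hab <- predict(sig_hab$model, sig_hab$table)
  prob_rad <- predict(sig_rad$model, sig_rad$table)
  prob_cli <- predict(sig_cli$model, sig_cli$table)

  # combined model is stacked on out-of-fold training scores, so the
  # component weights reflect held-out rather than resubstitution skill
  oof <- function(feats, seed_off) {
    tr_tab <- tab_h[tab_h$cohort == "train",
                    c("label", feats), drop = FALSE]
    nested_cross_validate(tr_tab, algorithm = algorithm,
                          outer_folds = 5L, inner_folds = lasso_folds,
                          seed = seed + seed_off)$predictions$prob
  }
  is_train <- tab_h$cohort == "train"
  lgt <- function(p) stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))
  comb_tab <- data.frame(cT = enc$clin_cT,
                         radiomics_score = lgt(prob_rad),
                         habitat_score = lgt(prob_hab),
                         label = tab_h$label,
                         cohort = tab_h$cohort)
  comb_train <- comb_tab[is_train, , drop = FALSE]
  comb_train$radiomics_score <- lgt(oof(sim$radiomics_features, 22L))
  comb_train$habitat_score <- lgt(oof(sim$habitat_features, 11L))
  mdl_comb <- fit_logistic_ridge_fallback(comb_train,
                                          c("cT", "radiomics_score",
                                            "habitat_score"))
  prob_comb <- predict(mdl_comb, comb_tab)

  scores <- data.frame(case_id = tab_h$case_id, cohort = tab_h$cohort,
                       center = tab_h$center, label = tab_h$label,
                       Clinical = prob_cli, Radiomics = prob_rad,
                       Habitat = prob_hab, Combined = prob_comb)
  models <- list(Clinical = sig_cli$model, Radiomics = sig_rad$model,
                 Habitat = sig_hab$model, Combined = mdl_comb)
  config <- list(seed = seed, algorithm = algorithm,
                 lasso_folds = lasso_folds, combat = combat,
                 selected = list(Habitat = sig_hab$selected,
                                 Radiomics = sig_rad$selected))
  assemble_report(scores, models, config, combined_train = comb_train)
}

#' Assemble the multi-cohort comparison report
#'
#' Collates, for every cohort x signature cell: AUC with DeLong 95% CI,
#' confusion metrics at the signature's frozen training threshold,
#' Hosmer-Lemeshow calibration and the decision curve; plus the pairwise
#' DeLong matrix per cohort and the configuration snapshot that suffices to
#' re-run the study. Errors if any requested cell is missing without an
#' explicit absence marker.
#'
#' @param scores data.frame with `case_id`, `cohort`, `label` and one
#'   probability column per signature.
#' @param models named list of `trained_model`s (thresholds are read from
#'   here).
#' @param config configuration snapshot stored verbatim in the report.
#' @param combined_train optional training rows of the combined model
#'   (enables [build_nomogram()] via `report$nomogram`).
#' @return object of class `study_report`.
#' @export
assemble_report <- function(scores, models, config = list(),
                            combined_train = NULL) {
  signatures <- names(models)
  cohorts <- unique(scores$cohort)
  miss <- setdiff(signatures, names(scores))
  if (length(miss) > 0L)
    stop("missing score column(s) without absence marker: ",
         paste(miss, collapse = ", "))
  metrics <- list(); rocs <- list(); delong <- list()
  calib <- list(); dca <- list()
  rows <- list()
  for (ch in cohorts) {
    sub <- scores[scores$cohort == ch, , drop = FALSE]
    rocs[[ch]] <- list()
    for (sg in signatures) {
      roc <- compute_roc_auc(sub[[sg]], sub$label)
      rocs[[ch]][[sg]] <- roc
      thr <- models[[sg]]$threshold
      cm <- classification_metrics(sub[[sg]], sub$label, thr)
      rows[[paste(ch, sg)]] <- data.frame(
        cohort = ch, signature = sg, n = nrow(sub),
        auc = roc$auc, auc_lo = roc$ci[1L], auc_hi = roc$ci[2L],
        threshold = thr,
        accuracy = cm[["accuracy"]], sensitivity = cm[["sensitivity"]],
        specificity = cm[["specificity"]], ppv = cm[["ppv"]],
        npv = cm[["npv"]], stringsAsFactors = FALSE)
      calib[[ch]][[sg]] <- tryCatch(
        suppressWarnings(calibration_hosmer_lemeshow(sub[[sg]], sub$label)),
        error = function(e) NULL)
      dca[[ch]][[sg]] <- decision_curve(sub[[sg]], sub$label)
    }
    delong[[ch]] <- delong_matrix(rocs[[ch]])
  }
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  nomogram <- NULL
  if (!is.null(combined_train) && "Combined" %in% signatures)
    nomogram <- tryCatch(build_nomogram(models$Combined, combined_train),
                         error = function(e) NULL)
  structure(list(metrics = metrics, delong = delong, calibration = calib,
                 dca = dca, scores = scores, config = config,
                 nomogram = nomogram),
            class = "study_report")
}

#' @exportS3Method print study_report
print.study_report <- function(x, ...) {
  cat("<study_report> AUC by cohort and signature\n")
  wide <- stats::reshape(x$metrics[c("cohort", "signature", "auc")],
                         idvar = "signature", timevar = "cohort",
                         direction = "wide")
  names(wide) <- sub("^auc\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a study report to JSON
#'
#' @param report a `study_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  out <- list(
    metrics = report$metrics,
    delong_p = lapply(report$delong, function(d) as.data.frame(d$p)),
    config = report$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
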