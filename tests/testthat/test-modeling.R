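# Standardization, LASSO selection, classifiers and the logistic
# signature layer.

sim_table <- function(n = 200, p = 10, informative = 0, effect = 1,
                      seed = 1, cohort = "train") {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  X <- matrix(rnorm(n * p), n, p)
  if (informative > 0)
    X[, seq_len(informative)] <- X[, seq_len(informative)] +
      effect * y
  colnames(X) <- sprintf("f%02d", seq_len(p))
  cbind(data.frame(case_id = as.character(seq_len(n)), cohort = cohort,
                   label = y, stringsAsFactors = FALSE),
        as.data.frame(X))
}

test_that("standardization uses training statistics only", {
  tab <- sim_table(60)
  tab$cohort <- rep(c("train", "test1"), each = 30)
  tab$f01 <- c(rep(c(1, 2, 3), 10), rnorm(30, 50, 5))
  out <- standardize_features(tab)
  tr <- out$table$f01[tab$cohort == "train"]
  expect_equal(mean(tr), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean((tr - mean(tr))^2)), 1, tolerance = 1e-10)
  expect_equal(sort(unique(round(tr, 4))), c(-1.2247, 0, 1.2247))
  # held-out rows use the training transform, not their own
  te <- out$table$f01[tab$cohort == "test1"]
  expect_gt(mean(te), 10)
  # zero-variance features are dropped with a warning
  tab$fz <- 1
  expect_warning(out2 <- standardize_features(tab), "zero-variance")
  expect_false("fz" %in% names(out2$table))
})

test_that("LASSO shrinkage endpoints and the soft-threshold closed form hold", {
  tab <- sim_table(100, p = 8, informative = 3, effect = 1.2, seed = 3)
  lr <- lasso_select(tab, folds = 5, seed = 3)
  # the largest lambda end of the path has no selected features
  expect_equal(sum(lr$coefficients[, 1] != 0), 0)
  expect_true(lr$lambda_opt %in% lr$lambda)

  # orthonormal design, squared-error mode: soft-thresholding oracle
  set.seed(4)
  n <- 64
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))[, 1:8] * sqrt(n)  # X'X/n = I
  beta <- c(3, -2, 1.5, 0, 0, 0, 0, 0)
  yq <- as.numeric(Q %*% beta)
  for (lam in c(0.5, 1.0, 2.1)) {
    fit <- glmnet::glmnet(Q, yq, family = "gaussian", alpha = 1,
                          lambda = lam, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-12)
    bls <- as.numeric(crossprod(Q, yq) / n)
    soft <- sign(bls) * pmax(abs(bls) - lam, 0)
    expect_equal(as.numeric(fit$beta), soft, tolerance = 1e-6)
  }
})

test_that("LASSO recovers planted informative features", {
  hits <- vapply(1:5, function(sd) {
    tab <- sim_table(300, p = 60, informative = 5, effect = 0.8, seed = sd)
    lr <- lasso_select(tab, folds = 10, seed = sd)
    sum(sprintf("f%02d", 1:5) %in% lr$selected)
  }, numeric(1L))
  expect_gte(median(hits), 4)
})

test_that("the penalized signature model reproduces the glmnet fit", {
  tab <- sim_table(150, p = 12, informative = 3, seed = 6)
  lr <- lasso_select(tab, folds = 5, seed = 6)
  mdl <- lasso_signature_model(lr, tab)
  p <- predict(mdl, tab)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mdl$train_auc, 0.7)
  manual <- plogis(lr$a0_opt +
                     as.matrix(tab[lr$features]) %*% lr$beta_opt)
  expect_equal(p, as.numeric(manual), tolerance = 1e-10)
})

test_that("every classifier separates a separable toy problem", {
  set.seed(9)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  tab <- data.frame(case_id = as.character(1:n), cohort = "train", label = y,
                    f1 = y * 4 + rnorm(n, 0, 0.2),
                    f2 = -y * 3 + rnorm(n, 0, 0.2))
  for (algo in c("logistic", "svm", "random_forest", "extra_trees",
                 "gradient_boosting")) {
    mdl <- suppressWarnings(fit_classifier(tab, algo, seed = 2))
    expect_equal(mdl$train_auc, 1.0, tolerance = 1e-8, label = algo)
    expect_true(all(predict(mdl, tab) >= 0 & predict(mdl, tab) <= 1))
  }
  expect_error(fit_classifier(tab, "neural_net"), "supported")
})

test_that("classifier training is deterministic given the seed", {
  tab <- sim_table(120, p = 6, informative = 2, seed = 10)
  for (algo in c("random_forest", "gradient_boosting")) {
    m1 <- fit_classifier(tab, algo, seed = 3)
    m2 <- fit_classifier(tab, algo, seed = 3)
    expect_identical(m1$hyperparameters, m2$hyperparameters)
    expect_equal(predict(m1, tab), predict(m2, tab), tolerance = 1e-12)
  }
})

test_that("prediction refuses mismatched feature schemas", {
  tab <- sim_table(80, p = 4, seed = 11)
  mdl <- suppressWarnings(fit_classifier(tab, "logistic", seed = 1))
  bad <- tab[, !(names(tab) %in% "f02")]
  expect_error(predict(mdl, bad), "f02")
})

test_that("permuted labels give chance-level training CV", {
  set.seed(12)
  tab <- sim_table(300, p = 10, informative = 0, seed = 12)
  mdl <- fit_classifier(tab, "gradient_boosting", seed = 12,
                        grid = expand.grid(max_depth = 2, nrounds = 30))
  cvres <- nested_cross_validate(tab, algorithm = "lasso", outer_folds = 5,
                                 inner_folds = 5, seed = 12)
  expect_lt(abs(cvres$auc - 0.5), 0.07)
})

test_that("nested CV tracks a planted binormal construction and nesting removes leakage", {
  # construction: 5 informative of 100, positives shifted so the Bayes
  # linear score has AUC = pnorm(delta * sqrt(5) / sqrt(2))
  delta <- 2 * qnorm(0.85)^2 / 5  # solve on the variance scale below
  del <- sqrt(2) * qnorm(0.85) / sqrt(5)
  tab <- sim_table(400, p = 100, informative = 5, effect = del, seed = 20)
  res <- nested_cross_validate(tab, algorithm = "lasso", outer_folds = 5,
                               inner_folds = 10, seed = 20)
  expect_lt(abs(res$auc - 0.85), 0.05)

  # leakage demonstration on pure noise: naive selection is optimistic
  diffs <- vapply(1:4, function(sd) {
    noise <- sim_table(150, p = 80, informative = 0, seed = 100 + sd)
    naive <- nested_cross_validate(noise, algorithm = "lasso",
                                   outer_folds = 4, inner_folds = 5,
                                   seed = sd, naive = TRUE)$auc
    nested <- nested_cross_validate(noise, algorithm = "lasso",
                                    outer_folds = 4, inner_folds = 5,
                                    seed = sd)$auc
    naive - nested
  }, numeric(1L))
  expect_gt(median(diffs), 0)
})

test_that("fitting never reads held-out labels", {
  tab <- sim_table(200, p = 10, informative = 3, seed = 30)
  tab$cohort <- rep(c("train", "test1"), each = 100)
  poisoned <- tab
  poisoned$label[poisoned$cohort == "test1"] <-
    1 - poisoned$label[poisoned$cohort == "test1"]
  st1 <- standardize_features(tab)
  st2 <- standardize_features(poisoned)
  tr1 <- st1$table[st1$table$cohort == "train", ]
  tr2 <- st2$table[st2$table$cohort == "train", ]
  l1 <- lasso_select(tr1, folds = 5, seed = 1)
  l2 <- lasso_select(tr2, folds = 5, seed = 1)
  expect_identical(l1$selected, l2$selected)
  m1 <- fit_classifier(tr1, "logistic", features = l1$selected, seed = 1)
  m2 <- fit_classifier(tr2, "logistic", features = l2$selected, seed = 1)
  expect_equal(coef(m1$fit), coef(m2$fit), tolerance = 1e-12)
})

test_that("univariable and multivariable logistic signatures report ORs", {
  set.seed(40)
  n <- 1000
  ct <- sample(c("T1", "T2", "T3"), n, replace = TRUE,
               prob = c(0.1, 0.35, 0.55))
  lin <- 0.6 * (as.numeric(factor(ct)) - 2)
  y <- rbinom(n, 1, plogis(-0.8 + lin))
  clin <- data.frame(label = y, cT = ct,
                     age = rnorm(n, 65, 6.5),
                     sex = sample(c("F", "M"), n, TRUE),
                     bmi = rnorm(n, 22.7, 2.4),
                     cN = sample(c("N0", "N1", "N2"), n, TRUE))
  fit <- fit_logistic_signatures(clin)
  uni <- fit$univariable
  expect_setequal(uni$covariate, c("age", "sex", "bmi", "cT", "cN"))
  ct_row <- uni[uni$covariate == "cT", ]
  expect_lt(ct_row$p_value, 0.05)
  expect_gt(ct_row$odds_ratio, 1.4)
  expect_true(ct_row$ci_low < ct_row$odds_ratio &
                ct_row$odds_ratio < ct_row$ci_high)
  expect_true("cT" %in% fit$multivariable$covariate)
  # null covariate: OR CI covers 1 (age was generated independent of y)
  age_row <- uni[uni$covariate == "age", ]
  expect_true(age_row$ci_low < 1 & age_row$ci_high > 1)
})

test_that("a null odds ratio is estimated near 1 on balanced data", {
  set.seed(41)
  n <- 1000
  clin <- data.frame(label = rbinom(n, 1, 0.5),
                     cT = sample(c("T1", "T2", "T3"), n, TRUE),
                     age = rnorm(n, 65, 6.5))
  fit <- fit_logistic_signatures(clin, covariates = c("age", "cT"))
  or <- fit$univariable$odds_ratio[fit$univariable$covariate == "cT"]
  expect_gt(or, 0.8); expect_lt(or, 1.25)
})

test_that("combined signature dominates its components when one is sufficient", {
  set.seed(42)
  n <- 600
  y <- rbinom(n, 1, 0.4)
  p_true <- plogis(qlogis(0.4) + 2 * (y - 0.4) + rnorm(n, 0, 0.5))
  clin <- data.frame(label = y,
                     cT = sample(c("T1", "T2", "T3"), n, TRUE))
  scores <- data.frame(radiomics_score = runif(n),
                       habitat_score = p_true)
  fit <- fit_logistic_signatures(clin, covariates = "cT", scores = scores)
  comb <- fit$combined
  tab <- data.frame(cT = as.numeric(factor(clin$cT)),
                    radiomics_score = scores$radiomics_score,
                    habitat_score = scores$habitat_score)
  pc <- predict(comb, tab)
  auc_comb <- compute_roc_auc(pc, y)$auc
  auc_hab <- compute_roc_auc(p_true, y)$auc
  expect_gte(auc_comb + 1e-8, auc_hab - 0.01)
})
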