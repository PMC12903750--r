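# ROC / AUC with DeLong inference, threshold metrics, calibration and
# decision-curve analysis. All deterministic given their inputs.

# Mid-rank (tie-aware) Mann-Whitney AUC.
auc_midrank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 (per positive), V01 (per negative),
# computed with mid-ranks so ties are handled consistently with the AUC.
delong_components <- function(scores, labels) {
  labels <- as.integer(labels)
  x <- scores[labels == 1L]  # positives
  y <- scores[labels == 0L]  # negatives
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01)
}

#' ROC curve with AUC and DeLong confidence interval
#'
#' AUC is the tie-aware Mann-Whitney statistic; its variance comes from the
#' DeLong structural components and the 95% CI from the normal
#' approximation (clipped to [0, 1]). ROC points are produced by a
#' threshold sweep over the observed scores.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels 0/1 outcomes, both classes present.
#' @return object of class `roc_result`: list with `points` (data.frame
#'   `threshold`, `fpr`, `tpr`), `auc`, `var_auc`, `ci` (length 2),
#'   `n_pos`, `n_neg`, and the structural components.
#' @export
compute_roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("both classes must be present")
  dc <- delong_components(scores, labels)
  m <- length(dc$v10); n <- length(dc$v01)
  var_auc <- stats::var(dc$v10) / m + stats::var(dc$v01) / n
  half <- stats::qnorm(0.975) * sqrt(max(var_auc, 0))
  ci <- c(max(0, dc$auc - half), min(1, dc$auc + half))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1L] >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0L] >= t), numeric(1L))
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = dc$auc, var_auc = var_auc, ci = ci,
                 n_pos = m, n_neg = n, v10 = dc$v10, v01 = dc$v01,
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @exportS3Method print roc_result
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci[1L], x$ci[2L], x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares two models scored on the same cases using the covariance of
#' their DeLong structural components; two-sided p from the normal
#' reference. A model compared with itself gives `delta = 0`, `p = 1`.
#'
#' @param roc_a,roc_b [compute_roc_auc()] results on identical cases and
#'   labels.
#' @return list with `delta_auc`, `z`, `p`, `var_delta`.
#' @export
delong_compare <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (roc_a$n_pos != roc_b$n_pos || roc_a$n_neg != roc_b$n_neg ||
      !identical(roc_a$labels, roc_b$labels))
    stop("paired DeLong needs identical cases and labels")
  m <- roc_a$n_pos; n <- roc_a$n_neg
  s10 <- stats::cov(cbind(roc_a$v10, roc_b$v10))
  s01 <- stats::cov(cbind(roc_a$v01, roc_b$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- roc_a$auc - roc_b$auc
  if (delta == 0) return(list(delta_auc = 0, z = 0, p = 1,
                              var_delta = var_delta))
  if (var_delta <= 0) return(list(delta_auc = delta, z = NA_real_,
                                  p = NA_real_, var_delta = var_delta))
  z <- delta / sqrt(var_delta)
  list(delta_auc = delta, z = z, p = 2 * stats::pnorm(-abs(z)),
       var_delta = var_delta)
}

#' Pairwise DeLong comparison matrix
#'
#' @param rocs named list of [compute_roc_auc()] results on the same cases.
#' @param adjust `"none"` (default; mirrors reporting AUC comparisons
#'   without multiplicity correction) or `"holm"`.
#' @return list with `p` (symmetric matrix of p-values, diagonal 1) and
#'   `delta` (antisymmetric AUC-difference matrix).
#' @export
delong_matrix <- function(rocs, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  k <- length(rocs)
  nm <- names(rocs)
  P <- matrix(1, k, k, dimnames = list(nm, nm))
  D <- matrix(0, k, k, dimnames = list(nm, nm))
  pv <- c(); pos <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    cmp <- delong_compare(rocs[[i]], rocs[[j]])
    P[i, j] <- P[j, i] <- cmp$p
    D[i, j] <- cmp$delta_auc; D[j, i] <- -cmp$delta_auc
    pv <- c(pv, cmp$p); pos <- c(pos, list(c(i, j)))
  }
  if (adjust == "holm" && length(pv) > 0L) {
    pa <- stats::p.adjust(pv, method = "holm")
    for (q in seq_along(pa)) {
      ij <- pos[[q]]
      P[ij[1], ij[2]] <- P[ij[2], ij[1]] <- pa[q]
    }
  }
  list(p = P, delta = D)
}

#' Confusion-table metrics at a fixed threshold
#'
#' Accuracy, sensitivity, specificity, PPV and NPV at the given probability
#' threshold (cases with `score >= threshold` called positive). Ratios with
#' zero denominators are reported as `NA`, not 0.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 outcomes.
#' @param threshold decision threshold.
#' @return named numeric vector including the confusion counts.
#' @export
classification_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = sdiv(tp, tp + fn),
    specificity = sdiv(tn, tn + fp),
    ppv = sdiv(tp, tp + fp),
    npv = sdiv(tn, tn + fn),
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Calibration bins and Hosmer-Lemeshow test
#'
#' Deciles-of-risk (equal-count) binning of the predicted probabilities;
#' the Hosmer-Lemeshow statistic is `sum (O - E)^2 / (E (1 - E / n_g))`
#' over bins, referred to chi-square with `bins - 2` degrees of freedom.
#' When the probabilities have fewer distinct quantile cuts than requested
#' bins, the bin count is reduced with a warning.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param bins requested bin count (default 10).
#' @return object of class `calibration_result`: list with `bins`
#'   (data.frame `mean_pred`, `obs_rate`, `count`, `events`), `statistic`,
#'   `df`, `p_value`.
#' @export
calibration_hosmer_lemeshow <- function(probs, labels, bins = 10L) {
  labels <- as.integer(labels)
  n <- length(probs)
  if (n < 2L * bins) stop("need n >= 2 * bins")
  grp <- equal_count_bins(probs, bins)
  g <- max(grp)
  if (g < bins)
    warning("fewer distinct probability cuts than bins; using ", g, " bins")
  O <- tapply(labels, grp, sum)
  ng <- tapply(labels, grp, length)
  E <- tapply(probs, grp, sum)
  mean_pred <- tapply(probs, grp, mean)
  obs_rate <- O / ng
  denom <- E * (1 - E / ng)
  keep <- denom > 0
  stat <- sum((O[keep] - E[keep])^2 / denom[keep])
  df <- g - 2L
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_
  structure(list(bins = data.frame(mean_pred = as.numeric(mean_pred),
                                   obs_rate = as.numeric(obs_rate),
                                   count = as.numeric(ng),
                                   events = as.numeric(O)),
                 statistic = stat, df = df, p_value = p),
            class = "calibration_result")
}

# Equal-count bin assignment by rank; ties in probs keep cases together
# only as far as the quantile cuts allow.
equal_count_bins <- function(x, bins) {
  qs <- unique(stats::quantile(x, probs = seq_len(bins - 1L) / bins,
                               type = 2))
  findInterval(x, qs, rightmost.closed = FALSE, left.open = FALSE) + 1L
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model at threshold probability `t`:
#' `NB(t) = TP/n - (FP/n) * t/(1-t)`, with the treat-all and treat-none
#' reference policies.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param t_grid thresholds, strictly inside (0, 1); default 0.01-0.80 by
#'   0.01.
#' @return object of class `dca_curve`: data.frame with `threshold`,
#'   `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(probs, labels, t_grid = seq(0.01, 0.80, by = 0.01)) {
  if (any(t_grid <= 0) || any(t_grid >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  nb_model <- vapply(t_grid, function(t) {
    pred <- probs >= t
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    tp / n - (fp / n) * t / (1 - t)
  }, numeric(1L))
  nb_all <- prev - (1 - prev) * t_grid / (1 - t_grid)
  out <- data.frame(threshold = t_grid, nb_model = nb_model,
                    nb_all = nb_all, nb_none = 0)
  class(out) <- c("dca_curve", "data.frame")
  out
}

#' Youden-optimal threshold from scores
#'
#' The probability cut maximizing sensitivity + specificity - 1 on the
#' supplied (training) data; ties resolve to the lowest threshold.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 outcomes.
#' @return threshold in (0, 1).
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  cand <- sort(unique(scores))
  if (length(cand) > 1L)
    cand <- (cand[-1L] + cand[-length(cand)]) / 2
  j <- vapply(cand, function(t) {
    mean(scores[labels == 1L] >= t) - mean(scores[labels == 0L] >= t)
  }, numeric(1L))
  thr <- cand[which.max(j)]
  min(max(thr, 1e-6), 1 - 1e-6)
}
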