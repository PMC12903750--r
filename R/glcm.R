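#' Gray-level co-occurrence matrix features
#'
#' For each of the 13 unique 3D directions at distance 1, counts
#' co-occurrences of gray levels over in-mask voxel pairs, accumulated
#' symmetrically (each pair contributes to `(i,j)` and `(j,i)`) and
#' normalized to a probability matrix. Features are computed per direction
#' and averaged. On a single-level ROI the degenerate identities hold:
#' Contrast 0, JointEnergy 1, Correlation 1 by convention.
#'
#' @param q a [discretize()]d ROI.
#' @return named numeric vector with `glcm_*` names.
#' @export
glcm_features <- function(q) {
  dirs <- directions_13()
  feats <- NULL
  used <- 0L
  for (r in seq_len(nrow(dirs))) {
    P <- glcm_matrix(q, dirs[r, ])
    if (is.null(P)) next
    f <- glcm_features_from_matrix(P)
    feats <- if (is.null(feats)) f else feats + f
    used <- used + 1L
  }
  if (used == 0L) stop("no co-occurring voxel pairs in any direction")
  feats / used
}

#' Co-occurrence matrix for one direction
#'
#' @param q a [discretize()]d ROI.
#' @param d integer length-3 offset.
#' @param normalize divide by the total count (default TRUE).
#' @return Ng x Ng symmetric matrix, or NULL if the direction has no pairs.
#' @export
glcm_matrix <- function(q, d, normalize = TRUE) {
  lv <- q$levels
  ng <- q$n_levels
  sh <- shift_array(lv, d, fill = 0L)
  ok <- lv > 0L & sh > 0L
  if (!any(ok)) return(NULL)
  i <- lv[ok]; j <- sh[ok]
  tab <- table(factor(i, levels = 1:ng), factor(j, levels = 1:ng))
  counts <- matrix(as.numeric(tab), ng, ng)
  counts <- counts + t(counts)  # symmetric accumulation
  if (normalize) counts / sum(counts) else counts
}

glcm_features_from_matrix <- function(P) {
  ng <- nrow(P)
  i <- matrix(1:ng, ng, ng)
  j <- t(i)
  px <- rowSums(P)
  mux <- sum(px * (1:ng))
  sigx <- sqrt(sum(px * ((1:ng) - mux)^2))
  contrast <- sum(P * (i - j)^2)
  correlation <- if (sigx > 0) sum(P * (i - mux) * (j - mux)) / sigx^2 else 1
  energy <- sum(P^2)
  pn <- P[P > 0]
  entropy <- -sum(pn * log2(pn))
  idm <- sum(P / (1 + (i - j)^2))
  cs <- sum(P * (i + j - 2 * mux)^3)
  cp <- sum(P * (i + j - 2 * mux)^4)
  c(glcm_Contrast = contrast,
    glcm_Correlation = correlation,
    glcm_JointEnergy = energy,
    glcm_JointEntropy = entropy,
    glcm_InverseDifferenceMoment = idm,
    glcm_ClusterShade = cs,
    glcm_ClusterProminence = cp)
}
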