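#' Gray-level run-length matrix features
#'
#' For each of the 13 unique 3D directions, maximal runs of equal gray level
#' along the direction are enumerated inside the mask (leaving the mask
#' breaks a run). Features are computed per direction from the run-length
#' matrix and averaged over directions.
#'
#' @param q a [discretize()]d ROI.
#' @return named numeric vector with `glrlm_*` names.
#' @export
glrlm_features <- function(q) {
  dirs <- directions_13()
  np <- sum(q$levels > 0L)
  feats <- NULL
  for (r in seq_len(nrow(dirs))) {
    R <- glrlm_matrix(q, dirs[r, ])
    f <- glrlm_features_from_matrix(R, np)
    feats <- if (is.null(feats)) f else feats + f
  }
  feats / nrow(dirs)
}

#' Run-length matrix for one direction
#'
#' @param q a [discretize()]d ROI.
#' @param d integer length-3 offset.
#' @return Ng x Lmax matrix of run counts (rows: gray level, cols: length).
#' @export
glrlm_matrix <- function(q, d) {
  lv <- q$levels
  dm <- dim(lv)
  idx <- which(lv > 0L)
  ng <- q$n_levels
  if (length(idx) == 0L) stop("empty mask")
  co <- voxel_coords(idx, dm)
  tpos <- co[, 1L] * d[1L] + co[, 2L] * d[2L] + co[, 3L] * d[3L]
  step <- sum(d * d)  # increment of tpos per unit move along the direction
  # line identity: |d|^2-scaled anchor, constant along the line and integer
  anch <- co * step - tpos %*% t(d)
  big <- max(dm) * 8L
  key <- (anch[, 1L] + 2L * big) +
    (anch[, 2L] + 2L * big) * (4L * big) +
    (anch[, 3L] + 2L * big) * (16L * big * big)
  lev <- lv[idx]
  o <- order(key, tpos)
  key <- key[o]; tpos <- tpos[o]; lev <- lev[o]
  n <- length(o)
  newrun <- c(TRUE, key[-1L] != key[-n] |
                tpos[-1L] != tpos[-n] + step |
                lev[-1L] != lev[-n])
  runid <- cumsum(newrun)
  rlen <- tabulate(runid)
  rlev <- lev[newrun]
  lmax <- max(rlen)
  R <- matrix(0, ng, lmax)
  for (k in seq_along(rlen)) R[rlev[k], rlen[k]] <- R[rlev[k], rlen[k]] + 1
  R
}

glrlm_features_from_matrix <- function(R, n_voxels) {
  nr <- sum(R)
  jl <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  p <- R / nr
  c(glrlm_ShortRunEmphasis = sum(p / jl^2),
    glrlm_LongRunEmphasis = sum(p * jl^2),
    glrlm_RunPercentage = nr / n_voxels,
    glrlm_GrayLevelNonUniformity = sum(rowSums(R)^2) / nr,
    glrlm_RunLengthNonUniformity = sum(colSums(R)^2) / nr)
}
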