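#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal gray level inside the mask;
#' the size-zone matrix is direction-free. Connected components are found on
#' the voxel adjacency graph (igraph).
#'
#' @param q a [discretize()]d ROI.
#' @return named numeric vector with `glszm_*` names.
#' @export
glszm_features <- function(q) {
  Z <- glszm_matrix(q)
  glszm_features_from_matrix(Z)
}

#' Size-zone matrix
#'
#' @param q a [discretize()]d ROI.
#' @return Ng x Smax matrix of zone counts (rows: gray level, cols: size).
#' @export
glszm_matrix <- function(q) {
  lv <- q$levels
  ng <- q$n_levels
  idx <- which(lv > 0L)
  if (length(idx) == 0L) stop("empty mask")
  pos <- array(0L, dim = dim(lv))
  pos[idx] <- seq_along(idx)
  dirs <- directions_13()
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    sh_lv <- shift_array(lv, dirs[r, ], fill = 0L)
    sh_pos <- shift_array(pos, dirs[r, ], fill = 0L)
    ok <- lv > 0L & sh_lv == lv & sh_lv > 0L
    if (any(ok)) {
      from <- c(from, pos[ok])
      to <- c(to, sh_pos[ok])
    }
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)
  zsize <- comp$csize
  zlev <- lv[idx][match(seq_len(comp$no), comp$membership)]
  smax <- max(zsize)
  Z <- matrix(0, ng, smax)
  for (k in seq_along(zsize)) Z[zlev[k], zsize[k]] <- Z[zlev[k], zsize[k]] + 1
  Z
}

glszm_features_from_matrix <- function(Z) {
  nz <- sum(Z)
  p <- Z / nz
  iL <- matrix(seq_len(nrow(Z)), nrow(Z), ncol(Z))
  jS <- matrix(seq_len(ncol(Z)), nrow(Z), ncol(Z), byrow = TRUE)
  mu_i <- sum(p * iL)
  pn <- p[p > 0]
  c(glszm_SmallAreaEmphasis = sum(p / jS^2),
    glszm_LargeAreaEmphasis = sum(p * jS^2),
    glszm_SmallAreaHighGrayLevelEmphasis = sum(p * iL^2 / jS^2),
    glszm_ZoneEntropy = -sum(pn * log2(pn)),
    glszm_GrayLevelVariance = sum(p * (iL - mu_i)^2))
}
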