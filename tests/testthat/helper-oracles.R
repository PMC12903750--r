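# Independent brute-force oracles: straightforward loop/flood-fill
# implementations kept deliberately separate from the package's vectorized
# code paths.

all_26_directions <- function() {
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d[rowSums(abs(d)) > 0, , drop = FALSE]
}

# Symmetric normalized co-occurrence matrix by exhaustive voxel-pair loop.
oracle_glcm <- function(lv, d, ng) {
  dm <- dim(lv)
  counts <- matrix(0, ng, ng)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- lv[i, j, k]
    if (a == 0) next
    i2 <- i + d[1]; j2 <- j + d[2]; k2 <- k + d[3]
    if (i2 < 1 || i2 > dm[1] || j2 < 1 || j2 > dm[2] ||
        k2 < 1 || k2 > dm[3]) next
    b <- lv[i2, j2, k2]
    if (b == 0) next
    counts[a, b] <- counts[a, b] + 1
    counts[b, a] <- counts[b, a] + 1
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

# Run-length matrix by walking each line voxel by voxel.
oracle_glrlm <- function(lv, d, ng) {
  dm <- dim(lv)
  inside <- function(p) all(p >= 1) && all(p <= dm)
  at <- function(p) lv[p[1], p[2], p[3]]
  runs_lev <- integer(0); runs_len <- integer(0)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    p <- c(i, j, k)
    if (at(p) == 0) next
    prev <- p - d
    # start of a run: predecessor outside grid/mask or different level
    if (inside(prev) && at(prev) == at(p)) next
    len <- 1L
    nxt <- p + d
    while (inside(nxt) && at(nxt) == at(p)) {
      len <- len + 1L
      nxt <- nxt + d
    }
    runs_lev <- c(runs_lev, at(p))
    runs_len <- c(runs_len, len)
  }
  R <- matrix(0, ng, max(runs_len))
  for (q in seq_along(runs_len))
    R[runs_lev[q], runs_len[q]] <- R[runs_lev[q], runs_len[q]] + 1
  R
}

# Size-zone matrix by flood fill over 26-connected equal-level components.
oracle_glszm <- function(lv, ng) {
  dm <- dim(lv)
  seen <- array(FALSE, dim = dm)
  dirs <- all_26_directions()
  zones_lev <- integer(0); zones_sz <- integer(0)
  idxs <- which(lv > 0)
  for (s in idxs) {
    if (seen[s]) next
    co <- arrayInd(s, dm)
    level <- lv[s]
    stack <- list(as.integer(co))
    seen[s] <- TRUE
    size <- 0L
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(dirs))) {
        q <- p + dirs[r, ]
        if (any(q < 1) || any(q > dm)) next
        if (seen[q[1], q[2], q[3]]) next
        if (lv[q[1], q[2], q[3]] != level) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1L]] <- as.integer(q)
      }
    }
    zones_lev <- c(zones_lev, level)
    zones_sz <- c(zones_sz, size)
  }
  Z <- matrix(0, ng, max(zones_sz))
  for (q in seq_along(zones_sz))
    Z[zones_lev[q], zones_sz[q]] <- Z[zones_lev[q], zones_sz[q]] + 1
  Z
}

# random quantized ROI on a dense block with a carved-out corner
random_quantized_roi <- function(dim3 = c(6, 6, 6), ng = 4, seed = 1) {
  set.seed(seed)
  lv <- array(sample.int(ng, prod(dim3), replace = TRUE), dim = dim3)
  # random holes make run/zone breaking nontrivial
  holes <- sample(prod(dim3), round(prod(dim3) * 0.2))
  lv[holes] <- 0L
  if (all(lv == 0L)) lv[1] <- 1L
  structure(list(levels = lv, n_levels = ng,
                 bin_edges = seq(0, ng), spacing_mm = c(1, 1, 1)),
            class = "quantized_roi")
}

make_sphere_mask <- function(radius_vox, spacing = c(1, 1, 1), pad = 3) {
  n <- 2 * (radius_vox + pad) + 1
  g <- seq_len(n) - (n + 1) / 2
  d <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
  roi_mask((d <= radius_vox) + 0, spacing)
}

make_block_volume <- function(values, spacing = c(1, 1, 1)) {
  image_volume(array(values, dim = c(length(values), 1, 1)), spacing)
}
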