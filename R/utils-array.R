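# Low-level 3D array helpers shared by the texture and habitat modules.
# All of these operate on plain arrays; geometry is handled by callers.

# The 13 unique 3D offsets at Chebyshev distance 1 (one from each +/- pair).
directions_13 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE]
  # keep one representative per antipodal pair: first nonzero component > 0
  keep <- apply(d, 1L, function(r) {
    nz <- r[r != 0]
    nz[1L] > 0
  })
  unname(d[keep, , drop = FALSE])
}

# Shift an array so out[i,j,k] = a[i+dx, j+dy, k+dz]; out-of-range -> fill.
shift_array <- function(a, d, fill = NA_real_) {
  dm <- dim(a)
  out <- array(fill, dim = dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dm[ax]
    if (d[ax] >= 0) {
      if (d[ax] >= n) return(out)
      dst[[ax]] <- seq_len(n - d[ax])
      src[[ax]] <- seq_len(n - d[ax]) + d[ax]
    } else {
      if (-d[ax] >= n) return(out)
      dst[[ax]] <- seq_len(n + d[ax]) - d[ax]
      src[[ax]] <- seq_len(n + d[ax])
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Sum of a over the (2r+1)^3 box centered at each voxel, zero outside the
# array. Summed-area (cumsum) construction: O(n) per axis.
box_sum <- function(a, r) {
  if (r < 0) stop("box radius must be >= 0")
  if (r == 0) return(a)
  for (ax in 1:3) a <- run_sum_axis(a, r, ax)
  a
}

run_sum_axis <- function(a, r, axis) {
  dm <- dim(a)
  n <- dm[axis]
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  x <- aperm(a, perm)
  dmx <- dim(x)
  x <- matrix(x, nrow = dmx[1L])
  cs <- apply(x, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = n)
  hi <- pmin(seq_len(n) + r, n)
  lo <- seq_len(n) - r - 1L
  res <- cs[hi, , drop = FALSE]
  pos <- lo >= 1L
  if (any(pos)) res[pos, ] <- res[pos, , drop = FALSE] - cs[lo[pos], , drop = FALSE]
  res <- array(res, dim = dmx)
  aperm(res, order(perm))
}

# Separable 1D convolution along each axis with a centered odd-length kernel.
# Edge handling: reflect (mirror without repeating the edge sample).
conv_separable <- function(a, kernels) {
  for (ax in 1:3) {
    k <- kernels[[ax]]
    if (length(k) == 1L) {
      a <- a * k
      next
    }
    r <- (length(k) - 1L) %/% 2L
    dm <- dim(a)
    n <- dm[ax]
    out <- array(0, dim = dm)
    for (off in -r:r) {
      idx <- seq_len(n) + off
      idx[idx < 1L] <- 2L - idx[idx < 1L]
      idx[idx > n] <- 2L * n - idx[idx > n]
      idx[idx < 1L] <- 1L
      idx[idx > n] <- n
      sl <- switch(ax,
        `1` = a[idx, , , drop = FALSE],
        `2` = a[, idx, , drop = FALSE],
        `3` = a[, , idx, drop = FALSE])
      out <- out + k[off + r + 1L] * sl
    }
    a <- out
  }
  a
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# voxel linear index <-> (i,j,k) helpers
voxel_coords <- function(idx, dm) {
  idx0 <- idx - 1L
  i <- idx0 %% dm[1L]
  j <- (idx0 %/% dm[1L]) %% dm[2L]
  k <- idx0 %/% (dm[1L] * dm[2L])
  cbind(i + 1L, j + 1L, k + 1L)
}
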