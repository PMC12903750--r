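# Image-filter variants feeding the extended feature set: pointwise
# square/squareroot/logarithm/exponential maps (normalized so output range is
# comparable to the input, following the common radiomics convention) and a
# single-level 3D separable Haar wavelet decomposition.

SUPPORTED_FILTERS <- c("square", "squareroot", "logarithm", "exponential", "wavelet")

#' Apply intensity-transform and wavelet filters to a volume
#'
#' Pointwise filters rescale so the output occupies a range comparable to
#' the input: `square` is x^2 scaled back to the original maximum absolute
#' value; `squareroot` is sqrt(|x|) scaled likewise (sign preserved);
#' `logarithm` is log(|x| + 1) rescaled; `exponential` is exp(x scaled to
#' max log range). `wavelet` yields the 8 subbands (LLL..HHH) of a
#' single-level 3D Haar decomposition, each mapped back to the input shape.
#'
#' @param v an [image_volume()].
#' @param filters character subset of
#'   `c("square","squareroot","logarithm","exponential","wavelet")`.
#' @return named list of [image_volume()]s; wavelet contributes entries
#'   `wavelet-LLL` .. `wavelet-HHH`.
#' @export
apply_image_filters <- function(v, filters = SUPPORTED_FILTERS) {
  bad <- setdiff(filters, SUPPORTED_FILTERS)
  if (length(bad) > 0L)
    stop("unknown filter(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(SUPPORTED_FILTERS, collapse = ", "))
  out <- list()
  x <- v$data
  amax <- max(abs(x))
  for (f in filters) {
    if (f == "wavelet") {
      sb <- haar_subbands(x)
      for (nm in names(sb)) {
        out[[paste0("wavelet-", nm)]] <-
          image_volume(sb[[nm]], v$spacing_mm, v$origin_mm)
      }
    } else {
      y <- switch(f,
        square = if (amax > 0) x^2 / amax else x,
        squareroot = sign(x) * sqrt(abs(x) * ifelse(amax > 0, amax, 1)) /
          ifelse(amax > 0, 1, 1),
        logarithm = if (amax > 0) sign(x) * log(abs(x) + 1) * amax / log(amax + 1)
                    else x,
        exponential = if (amax > 0) exp(x * log(amax) / amax) else exp(x))
      out[[f]] <- image_volume(y, v$spacing_mm, v$origin_mm)
    }
  }
  out
}

# Single-level 3D Haar: along each axis, pairs (a,b) map to low (a+b)/sqrt(2)
# and high (a-b)/sqrt(2); odd-length axes are padded by edge replication.
# Subbands are upsampled back to the input shape by sample repetition so
# feature extraction can reuse the original mask.
haar_subbands <- function(x) {
  dm <- dim(x)
  bands <- list(x)
  bnames <- ""
  for (ax in 1:3) {
    nxt <- list()
    nnames <- character(0)
    for (bi in seq_along(bands)) {
      lh <- haar_axis(bands[[bi]], ax)
      nxt <- c(nxt, list(lh$low), list(lh$high))
      nnames <- c(nnames, paste0(bnames[bi], "L"), paste0(bnames[bi], "H"))
    }
    bands <- nxt
    bnames <- nnames
  }
  names(bands) <- bnames
  # upsample each subband back to dm
  lapply(bands, function(b) {
    for (ax in 1:3) {
      idx <- rep(seq_len(dim(b)[ax]), each = 2L)[seq_len(dm[ax])]
      b <- index_axis(b, ax, idx)
    }
    b
  })
}

haar_axis <- function(a, ax) {
  n <- dim(a)[ax]
  if (n %% 2L == 1L) {
    a <- index_axis(a, ax, c(seq_len(n), n))  # edge-replicate pad
    n <- n + 1L
  }
  odd <- index_axis(a, ax, seq(1L, n, by = 2L))
  evn <- index_axis(a, ax, seq(2L, n, by = 2L))
  list(low = (odd + evn) / sqrt(2), high = (odd - evn) / sqrt(2))
}
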