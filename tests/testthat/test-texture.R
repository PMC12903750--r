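# Texture feature families: discretization, first-order, shape, gray-level
# matrices with brute-force oracles, and the image filters.

test_that("discretization follows the fixed-bin-number convention", {
  vals <- c(0, 255, 128, 7.9, 8.1)
  v <- make_block_volume(vals)
  m <- roi_mask(array(1, c(length(vals), 1, 1)), 1)
  q <- discretize(v, m, 32)
  lv <- q$levels[, 1, 1]
  expect_equal(lv[1], 1L)   # min -> level 1
  expect_equal(lv[2], 32L)  # max -> level 32
  expect_equal(diff(q$bin_edges)[1], 255 / 32, tolerance = 1e-12)

  # hand-binned example: two clusters of values, 2 bins
  v6 <- make_block_volume(c(1, 2, 3, 10, 11, 12))
  m6 <- roi_mask(array(1, c(6, 1, 1)), 1)
  q6 <- discretize(v6, m6, 2)
  expect_equal(as.integer(q6$levels[, 1, 1]), c(1L, 1L, 1L, 2L, 2L, 2L))

  const <- make_block_volume(rep(4, 5))
  mc <- roi_mask(array(1, c(5, 1, 1)), 1)
  qc <- discretize(const, mc, 32)
  expect_true(all(qc$levels[qc$levels > 0] == 1L))
  expect_equal(qc$n_levels, 1L)
  expect_error(discretize(v6, roi_mask(array(0, c(6, 1, 1)), 1)), "empty")
})

test_that("first-order features match hand arithmetic and degenerate rules", {
  v <- make_block_volume(c(2, 4, 4, 4, 5, 5, 7, 9))
  m <- roi_mask(array(1, c(8, 1, 1)), 1)
  fo <- first_order_features(v, m)
  expect_equal(unname(fo["firstorder_Mean"]), 5)
  expect_equal(unname(fo["firstorder_Variance"]), 4)  # population variance
  expect_equal(unname(fo["firstorder_Energy"]), sum(c(2, 4, 4, 4, 5, 5, 7, 9)^2))

  sym <- first_order_features(make_block_volume(c(1, 2, 3)),
                              roi_mask(array(1, c(3, 1, 1)), 1))
  expect_equal(unname(sym["firstorder_Skewness"]), 0)

  const <- first_order_features(make_block_volume(rep(3, 6)),
                                roi_mask(array(1, c(6, 1, 1)), 1))
  expect_equal(unname(const["firstorder_Variance"]), 0)
  expect_equal(unname(const["firstorder_Entropy"]), 0)
  expect_equal(unname(const["firstorder_Skewness"]), 0)
})

test_that("shape features match closed-form solids", {
  single <- array(0, c(3, 3, 3)); single[2, 2, 2] <- 1
  sf <- shape_features(roi_mask(single, c(1, 1, 1)))
  expect_equal(unname(sf["shape_VoxelVolume"]), 1)

  sph <- make_sphere_mask(10)
  sfs <- shape_features(sph)
  expect_gte(unname(sfs["shape_Sphericity"]), 0.95)
  expect_lte(unname(sfs["shape_Sphericity"]), 1.0)
  expect_equal(unname(sfs["shape_Maximum3DDiameter"]), 20, tolerance = 0.1)
  expect_equal(unname(sfs["shape_Elongation"]), 1, tolerance = 0.02)

  cube <- array(0, c(16, 16, 16)); cube[4:13, 4:13, 4:13] <- 1
  sfc <- shape_features(roi_mask(cube, c(1, 1, 1)))
  expect_equal(unname(sfc["shape_VoxelVolume"]), 1000)
  expect_equal(unname(sfc["shape_Sphericity"]),
               pi^(1 / 3) * (6 * 1000)^(2 / 3) / 600, tolerance = 0.15)
})

test_that("GLCM degenerate identities and checkerboard example hold", {
  const <- make_block_volume(rep(7, 8))
  mc <- roi_mask(array(1, c(8, 1, 1)), 1)
  f <- glcm_features(discretize(const, mc, 8))
  expect_equal(unname(f["glcm_Contrast"]), 0)
  expect_equal(unname(f["glcm_JointEnergy"]), 1)
  expect_equal(unname(f["glcm_Correlation"]), 1)

  cb <- array(outer(1:4, 1:4, function(i, j) (i + j) %% 2) * 100, c(4, 4, 1))
  q <- discretize(image_volume(cb, c(1, 1, 1)),
                  roi_mask(array(1, c(4, 4, 1)), c(1, 1, 1)), 2)
  P <- glcm_matrix(q, c(1, 0, 0))
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2), ignore_attr = TRUE)
  f2 <- habrad:::glcm_features_from_matrix(P)
  expect_equal(unname(f2["glcm_Contrast"]), 1)
})

test_that("GLRLM matches run enumeration on simple patterns", {
  const <- image_volume(array(5, c(4, 4, 1)), c(1, 1, 1))
  m <- roi_mask(array(1, c(4, 4, 1)), c(1, 1, 1))
  q <- discretize(const, m, 4)
  R <- glrlm_matrix(q, c(1, 0, 0))
  expect_equal(sum(R), 4)       # 4 runs
  expect_equal(R[1, 4], 4)      # all of length 4
  fr <- habrad:::glrlm_features_from_matrix(R, 16)
  expect_equal(unname(fr["glrlm_LongRunEmphasis"]), 16)
  expect_equal(unname(fr["glrlm_ShortRunEmphasis"]), 1 / 16)

  # checkerboard: along any direction that flips parity (odd component
  # sum) every run has length 1
  cb <- array(outer(1:4, 1:4, function(i, j) (i + j) %% 2) * 100, c(4, 4, 1))
  qcb <- discretize(image_volume(cb, c(1, 1, 1)), m, 2)
  for (d in list(c(1, 0, 0), c(0, 1, 0))) {
    Rcb <- glrlm_matrix(qcb, d)
    fd <- habrad:::glrlm_features_from_matrix(Rcb, 16)
    expect_equal(unname(fd["glrlm_LongRunEmphasis"]), 1)
    expect_equal(unname(fd["glrlm_RunPercentage"]), 1)
  }
})

test_that("GLSZM zones follow 26-connectivity and the direct summation", {
  # constant ROI: one zone of size N, LargeAreaEmphasis N^2
  const <- image_volume(array(2, c(3, 3, 3)), c(1, 1, 1))
  m <- roi_mask(array(1, c(3, 3, 3)), c(1, 1, 1))
  q <- discretize(const, m, 4)
  f <- glszm_features(q)
  expect_equal(unname(f["glszm_LargeAreaEmphasis"]), 27^2)

  # 3D checkerboard: each level forms a single diagonal-connected zone
  dm <- c(4, 4, 4)
  par <- array(0, dm)
  for (i in 1:4) for (j in 1:4) for (k in 1:4) par[i, j, k] <- (i + j + k) %% 2
  qcb <- discretize(image_volume(par * 10, c(1, 1, 1)),
                    roi_mask(array(1, dm), c(1, 1, 1)), 2)
  Z <- glszm_matrix(qcb)
  expect_equal(sum(Z), 2)

  # hand-built toy: direct-summation identity for SAHGLE
  lv <- array(0L, c(5, 1, 1))
  lv[, 1, 1] <- c(1L, 1L, 0L, 2L, 3L)
  qt <- structure(list(levels = lv, n_levels = 3L, bin_edges = 0:3,
                       spacing_mm = c(1, 1, 1)), class = "quantized_roi")
  Zt <- glszm_matrix(qt)
  p <- Zt / sum(Zt)
  manual <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    manual <- manual + p[i, j] * i^2 / j^2
  expect_equal(unname(glszm_features(qt)["glszm_SmallAreaHighGrayLevelEmphasis"]),
               manual, tolerance = 1e-10)
})

test_that("matrices equal exhaustive-enumeration oracles on random ROIs", {
  dirs <- habrad:::directions_13()
  for (seed in 1:8) {
    q <- random_quantized_roi(seed = seed)
    for (r in c(1, 5, 13)) {
      P <- glcm_matrix(q, dirs[r, ])
      O <- oracle_glcm(q$levels, dirs[r, ], q$n_levels)
      expect_equal(P, O, tolerance = 1e-12)
      R <- glrlm_matrix(q, dirs[r, ])
      OR <- oracle_glrlm(q$levels, dirs[r, ], q$n_levels)
      expect_equal(unname(R), unname(OR))
    }
    Z <- glszm_matrix(q)
    OZ <- oracle_glszm(q$levels, q$n_levels)
    expect_equal(unname(Z), unname(OZ))
  }
})

test_that("direction-averaged GLCM/GLRLM are invariant to 90-degree rotation", {
  set.seed(11)
  lv <- array(sample.int(3, 5^3, replace = TRUE), c(5, 5, 5))
  q1 <- structure(list(levels = lv, n_levels = 3L, bin_edges = 0:3,
                       spacing_mm = c(1, 1, 1)), class = "quantized_roi")
  rot <- aperm(lv, c(2, 1, 3))[5:1, , ]  # 90-degree rotation about z
  q2 <- structure(list(levels = rot, n_levels = 3L, bin_edges = 0:3,
                       spacing_mm = c(1, 1, 1)), class = "quantized_roi")
  expect_equal(glcm_features(q1), glcm_features(q2), tolerance = 1e-8)
  expect_equal(glrlm_features(q1), glrlm_features(q2), tolerance = 1e-8)
})

test_that("normalized texture matrices sum to one and emphases are nonnegative", {
  dirs <- habrad:::directions_13()
  for (seed in c(3, 4)) {
    q <- random_quantized_roi(seed = seed)
    P <- glcm_matrix(q, dirs[2, ])
    expect_equal(sum(P), 1, tolerance = 1e-10)
    expect_equal(P, t(P), tolerance = 1e-12)
    f <- c(glcm_features(q), glrlm_features(q), glszm_features(q))
    emph <- f[grep("Emphasis|Energy|Percentage", names(f))]
    expect_true(all(emph >= 0))
  }
})

test_that("image filters behave on constants and the Haar bank", {
  const <- image_volume(array(3, c(4, 4, 4)), c(1, 1, 1))
  out <- apply_image_filters(const, c("square", "wavelet"))
  expect_true(all(abs(out$square$data - out$square$data[1]) < 1e-12))
  # vanishing moments: all detail subbands of a constant are zero
  for (nm in c("wavelet-HLL", "wavelet-LHL", "wavelet-LLH", "wavelet-HHL",
               "wavelet-HLH", "wavelet-LHH", "wavelet-HHH"))
    expect_true(all(abs(out[[nm]]$data) < 1e-12), info = nm)
  expect_true(all(out$`wavelet-LLL`$data > 0))

  # Haar filter bank on a 2-periodic pattern: analytic subband values.
  # Along x the pairs (2,6) give low (2+6)/sqrt(2) and high (2-6)/sqrt(2);
  # the length-1 y/z axes each contribute a factor sqrt(2) to the low band.
  pat <- array(rep(c(2, 6), 4), c(8, 1, 1))
  sb <- habrad:::haar_subbands(pat)
  expect_equal(unique(as.vector(sb$LLL)), (2 + 6) / sqrt(2) * 2,
               tolerance = 1e-12)
  expect_equal(unique(as.vector(sb$HLL)), (2 - 6) / sqrt(2) * 2,
               tolerance = 1e-12)
  for (nm in c("LHL", "LLH", "HHL", "HLH", "LHH", "HHH"))
    expect_true(all(abs(sb[[nm]]) < 1e-12), info = nm)
  expect_error(apply_image_filters(const, "lbp"), "unknown filter")
})

test_that("case-level extraction respects configuration and determinism", {
  set.seed(5)
  v <- image_volume(array(rnorm(6^3, 100, 20), c(6, 6, 6)), c(1, 1, 1))
  m <- roi_mask(array(1, c(6, 6, 6)), c(1, 1, 1))
  fo_only <- extract_case_features(v, m, extraction_config("firstorder"))
  expect_true(all(grepl("^original_firstorder_", names(fo_only))))
  full <- extract_case_features(v, m)
  expect_true(any(grepl("glcm", names(full))))
  expect_identical(full, extract_case_features(v, m))
  wav <- extract_case_features(v, m, extraction_config(
    families = c("firstorder", "glrlm"), filters = c("original", "wavelet")))
  expect_true(any(grepl("^wavelet-LLH_glrlm_", names(wav))))
})
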