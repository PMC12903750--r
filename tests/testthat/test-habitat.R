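# Voxel descriptor maps, CH-guided k-means habitat partitioning and
# per-habitat feature extraction.

test_that("voxel feature map is a bijection over in-mask voxels", {
  ph <- generate_phantom(phantom_spec(seed = 1))
  fm <- compute_voxel_feature_map(ph$volume, ph$mask)
  expect_equal(nrow(fm$features), n_mask_voxels <- sum(ph$mask$data != 0))
  expect_equal(length(fm$index), n_mask_voxels)
  expect_true(all(is.finite(fm$features)))
})

test_that("constant volumes give identical descriptors that z-score to zero", {
  v <- image_volume(array(9, c(8, 8, 8)), c(1, 1, 1))
  md <- array(0, c(8, 8, 8)); md[3:6, 3:6, 3:6] <- 1
  m <- roi_mask(md, c(1, 1, 1))
  fm <- compute_voxel_feature_map(v, m)
  expect_true(all(fm$features == 0))
  expect_true(all(apply(fm$raw, 2, function(x) length(unique(x))) >= 1))
})

test_that("a two-region phantom yields a bimodal local-mean channel", {
  ps <- phantom_spec(n_habitats = 2, habitat_means = c(50, 200),
                     habitat_sds = c(5, 5), seed = 4)
  ph <- generate_phantom(ps)
  fm <- compute_voxel_feature_map(ph$volume, ph$mask)
  de <- density(fm$raw[, "local_mean"], bw = 8)
  peaks <- de$x[which(diff(sign(diff(de$y))) == -2) + 1]
  expect_true(min(abs(peaks - 50)) < 15)
  expect_true(min(abs(peaks - 200)) < 15)
})

test_that("CH score matches the direct-summation definition on small data", {
  set.seed(2)
  X <- rbind(matrix(rnorm(100, 0), ncol = 2),
             matrix(rnorm(100, 4), ncol = 2))
  lab <- rep(1:2, each = 50)
  got <- calinski_harabasz(X, lab)
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (c in 1:2) {
    Xi <- X[lab == c, ]
    ci <- colMeans(Xi)
    B <- B + 50 * sum((ci - grand)^2)
    for (r in seq_len(nrow(Xi))) W <- W + sum((Xi[r, ] - ci)^2)
  }
  expect_equal(got, (B / 1) / (W / 98), tolerance = 1e-10)
})

test_that("planted descriptor blobs are recovered with the right K", {
  skip_if_not_installed("mclust")
  set.seed(5)
  # synthetic descriptor-space blobs routed through the partition machinery
  blob <- function(mu, n) sweep(matrix(rnorm(n * 5, 0, 0.05), n, 5), 2, mu, "+")
  X <- rbind(blob(c(0, 0, 0, 0, 0), 80), blob(c(3, 0, 0, 0, 0), 80),
             blob(c(0, 3, 0, 0, 0), 80), blob(c(3, 3, 0, 0, 0), 80))
  fm <- structure(list(coords = cbind(seq_len(320), 1L, 1L),
                       index = seq_len(320), features = X, raw = X,
                       intensity = X[, 1], window_radius = 1L,
                       dim = c(320L, 1L, 1L), spacing_mm = c(1, 1, 1)),
                  class = "voxel_feature_map")
  hm <- partition_habitats(fm, seed = 5, channel_weights = rep(1, 5))
  expect_equal(hm$k, 4)
  truth <- rep(1:4, each = 80)
  ari <- mclust::adjustedRandIndex(truth, hm$labels[fm$index])
  expect_gte(ari, 0.99)
  # 2 blobs: K = 2 with perfect agreement
  X2 <- rbind(blob(rep(0, 5), 100), blob(rep(2.5, 5), 100))
  fm2 <- fm; fm2$features <- X2; fm2$raw <- X2
  fm2$intensity <- X2[, 1]
  fm2$coords <- cbind(seq_len(200), 1L, 1L); fm2$index <- seq_len(200)
  fm2$dim <- c(200L, 1L, 1L)
  hm2 <- partition_habitats(fm2, seed = 6, channel_weights = rep(1, 5))
  expect_equal(hm2$k, 2)
  expect_equal(mclust::adjustedRandIndex(rep(1:2, each = 100),
                                         hm2$labels[fm2$index]), 1)
})

test_that("partitioning is deterministic and partitions the mask exactly", {
  ph <- generate_phantom(phantom_spec(seed = 9))
  fm <- compute_voxel_feature_map(ph$volume, ph$mask)
  h1 <- partition_habitats(fm, seed = 9)
  h2 <- partition_habitats(fm, seed = 9)
  expect_identical(h1$labels, h2$labels)
  expect_identical(h1$k, h2$k)
  inm <- ph$mask$data != 0
  expect_true(all(h1$labels[inm] >= 1))
  expect_true(all(h1$labels[!inm] == 0))
  expect_setequal(unique(as.vector(h1$labels[inm])), seq_len(h1$k))
})

test_that("habitat labels are ordered by ascending mean intensity", {
  ph <- generate_phantom(phantom_spec(seed = 12))
  fm <- compute_voxel_feature_map(ph$volume, ph$mask)
  hm <- partition_habitats(fm, seed = 12)
  mus <- vapply(seq_len(hm$k), function(k)
    mean(ph$volume$data[hm$labels == k]), numeric(1L))
  expect_true(all(diff(mus) > 0))
})

test_that("habitat recovery on the 4-habitat phantom is near-perfect", {
  skip_if_not_installed("mclust")
  ph <- generate_phantom(phantom_spec(seed = 21))
  fm <- compute_voxel_feature_map(ph$volume, ph$mask)
  hm <- partition_habitats(fm, seed = 21)
  expect_equal(hm$k, 4)
  inm <- ph$mask$data != 0
  ari <- mclust::adjustedRandIndex(ph$truth_habitats$labels[inm],
                                   hm$labels[inm])
  expect_gte(ari, 0.95)
})

test_that("K = 1 habitat features equal whole-tumor features", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  hm1 <- structure(list(labels = (ph$mask$data != 0) + 0L, k = 1L,
                        ch_scores = NULL, dim = dim(ph$mask$data),
                        spacing_mm = ph$mask$spacing_mm),
                   class = "habitat_map")
  hf <- extract_habitat_features(ph$volume, hm1)
  q <- discretize(ph$volume, ph$mask, 32)
  whole <- c(first_order_features(ph$volume, ph$mask), glcm_features(q),
             glrlm_features(q), glszm_features(q))
  for (nm in names(whole)) {
    expect_equal(unname(hf[paste0("original_", nm, "_hab1")]),
                 unname(whole[nm]), tolerance = 1e-12, label = nm)
  }
  expect_equal(unname(hf["habitat_volume_fraction_hab1"]), 1)
})

test_that("two uniform habitats yield their construction values", {
  dm <- c(10, 10, 3)
  lab <- array(0L, dm); lab[2:5, 2:9, 1:3] <- 1L; lab[6:9, 2:9, 1:3] <- 2L
  vol <- array(0, dm)
  vol[lab == 1L] <- 30; vol[lab == 2L] <- 170
  v <- image_volume(vol, c(1, 1, 1))
  hm <- structure(list(labels = lab, k = 2L, ch_scores = NULL, dim = dm,
                       spacing_mm = c(1, 1, 1)), class = "habitat_map")
  hf <- extract_habitat_features(v, hm)
  expect_equal(unname(hf["original_firstorder_Mean_hab1"]), 30)
  expect_equal(unname(hf["original_firstorder_Mean_hab2"]), 170)
  expect_equal(unname(hf["original_glcm_Contrast_hab1"]), 0)
  expect_equal(unname(hf["original_glcm_Contrast_hab2"]), 0)
  fr <- hf[grep("volume_fraction", names(hf))]
  expect_equal(sum(fr), 1, tolerance = 1e-10)
})

test_that("small habitats yield flagged missing values with a stable schema", {
  dm <- c(8, 8, 3)
  lab <- array(0L, dm); lab[2:7, 2:7, 1:3] <- 1L; lab[1, 1, 1] <- 2L
  vol <- array(rnorm(prod(dm), 100, 10), dm)
  v <- image_volume(vol, c(1, 1, 1))
  hm <- structure(list(labels = lab, k = 2L, ch_scores = NULL, dim = dm,
                       spacing_mm = c(1, 1, 1)), class = "habitat_map")
  hf <- extract_habitat_features(v, hm, min_voxels = 10)
  h1 <- hf[grep("_hab1$", names(hf))]
  h2 <- hf[grep("_hab2$", names(hf))]
  expect_true(all(is.finite(h1)))
  expect_true(all(is.na(h2[grep("firstorder|glcm", names(h2))])))
  expect_equal(length(h1), length(h2))
})

test_that("cohort habitat-count harmonization takes the modal optimum", {
  fmaps <- lapply(1:3, function(sd) {
    ph <- generate_phantom(phantom_spec(seed = sd))
    compute_voxel_feature_map(ph$volume, ph$mask)
  })
  out <- harmonize_habitat_count(fmaps, k_min = 2, k_max = 6, seed = 1,
                                 nstart = 5)
  expect_equal(out$k_star, as.integer(names(which.max(table(out$optima)))))
  expect_true(all(vapply(out$maps, function(m) m$k, integer(1L)) ==
                    out$k_star))
  pc <- harmonize_habitat_count(fmaps, strategy = "per-case", k_min = 2,
                                k_max = 6, seed = 1, nstart = 5)
  expect_true(is.na(pc$k_star))
  expect_error(harmonize_habitat_count(fmaps, strategy = "bogus"))
})
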