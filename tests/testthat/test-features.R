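# Intensity / contrast channels and feature-matrix assembly.

test_that("intensity quantisation follows the per-image min-max rule", {
  expect_true(all(quantize_intensity(matrix(7, 32, 32), 1, 10) == 0L))
  ramp <- matrix(seq_len(100), 100, 100, byrow = TRUE)
  q <- quantize_intensity(ramp, 0.5, 10L)
  interior <- q[50, 10:90]
  frac <- tabulate(q + 1L, 10) / length(q)
  expect_true(all(q %in% 0:9))
  expect_true(all(abs(frac - 0.1) < 0.05))   # deciles of a linear ramp
  expect_true(all(diff(interior) >= 0))      # monotone along the ramp
})

test_that("contrast filter is a windowed coefficient of variation", {
  expect_lt(max(contrast_filter(matrix(3, 32, 32), 2)), 1e-6)
  chk <- matrix(0.5, 64, 64)
  chk[(row(chk) + col(chk)) %% 2 == 1] <- 1.5
  cm <- contrast_filter(chk, 8)
  # weighted sd/mean of the {0.5, 1.5} checkerboard: 0.5 / 1.0
  expect_equal(mean(cm[24:40, 24:40]), 0.5, tolerance = 0.02)
  set.seed(14)
  img <- matrix(runif(32 * 32, 1, 2), 32, 32)
  expect_equal(contrast_filter(img * 3.5, 2), contrast_filter(img, 2),
               tolerance = 1e-10)
  expect_true(all(contrast_filter(img, 2) >= 0))
})

test_that("feature dimensions follow the channel/scale bookkeeping", {
  expect_identical(feature_dim(feature_config(scales = c(1, 2, 4),
                                              window = 20L)), 21L)
  expect_identical(feature_dim(feature_config(scales = c(1, 2, 4, 8, 16),
                                              window = 1L)), 5L)
  cfg <- feature_config(scales = c(1, 2), window = 15L,
                        channels = c("bifs", "intensity", "contrast"))
  expect_identical(feature_dim(cfg), 2L * 7L + 2L * 10L + 2L * 10L)
})

test_that("assembled features honour the config and are deterministic", {
  set.seed(15)
  img <- matrix(runif(48 * 48, 0, 100), 48, 48)
  cfg <- feature_config(scales = c(1, 2), window = 7L,
                        channels = c("bifs", "intensity"))
  fm1 <- assemble_features(img, cfg)
  fm2 <- assemble_features(img, cfg)
  expect_identical(fm1$vectors, fm2$vectors)
  expect_identical(ncol(fm1$vectors), feature_dim(cfg))
  expect_identical(length(fm1$feature_names), feature_dim(cfg))
  expect_false(anyDuplicated(fm1$feature_names) > 0)
  expect_true(all(is.finite(fm1$vectors)))
  # per-channel-scale histogram sub-vectors sum to 1
  bif1 <- fm1$vectors[, grep("^bifs\\.s1\\.", fm1$feature_names)]
  int2 <- fm1$vectors[, grep("^intensity\\.s2\\.", fm1$feature_names)]
  expect_lt(max(abs(rowSums(bif1) - 1)), 1e-6)
  expect_lt(max(abs(rowSums(int2) - 1)), 1e-6)
})

test_that("the w = 1 baseline emits one raw label per channel-scale", {
  set.seed(16)
  img <- matrix(runif(32 * 32, 0, 100), 32, 32)
  cfg <- feature_config(scales = c(1, 2, 4), window = 1L)
  fm <- assemble_features(img, cfg)
  expect_identical(ncol(fm$vectors), 3L)
  b <- compute_bifs(img, 2, 0.03)
  expect_equal(fm$vectors[, "bifs.s2.value"], as.numeric(b$labels))
})

test_that("column order is channel-major then scale-ascending", {
  cfg <- feature_config(scales = c(2, 8), window = 5L,
                        channels = c("contrast", "bifs"))
  nm <- assemble_features(matrix(runif(32 * 32), 32), cfg)$feature_names
  expect_identical(nm[1], "bifs.s2.b01")
  expect_identical(nm[8], "bifs.s8.b01")
  expect_identical(nm[15], "contrast.s2.b01")
})

test_that("configuration validation rejects bad settings", {
  expect_error(feature_config(scales = numeric(0)))
  expect_error(feature_config(scales = c(2, 1)))
  expect_error(feature_config(window = 0))
  expect_error(feature_config(channels = "wavelet"))
})
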