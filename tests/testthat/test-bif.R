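# Derivative-of-Gaussian responses and BIF classification.

test_that("responses to constant and linear images match analytic values", {
  const <- matrix(5, 32, 32)
  r <- dtg_responses(const, 2)
  expect_equal(max(abs(r$s00 - 5)), 0, tolerance = 1e-12)
  for (nm in c("s10", "s01", "s20", "s11", "s02"))
    expect_lt(max(abs(r[[nm]])), 1e-12)

  ramp <- matrix(seq_len(32), 32, 32, byrow = TRUE)   # I(x, y) = x
  r <- dtg_responses(ramp, 2)
  interior <- 10:23
  expect_equal(r$s10[interior, interior],
               matrix(2, 14, 14), tolerance = 1e-3)
  expect_lt(max(abs(r$s20[interior, interior])), 1e-6)
  expect_lt(max(abs(r$s11[interior, interior])), 1e-6)
  expect_lt(max(abs(r$s02[interior, interior])), 1e-6)
})

test_that("Gaussian bump centre response matches the closed form", {
  # bump of sd 3 filtered at sigma_b = 3: the smoothed image is
  # 0.5 * exp(-r^2 / 36), whose scale-normalised Laplacian at the centre
  # is 9 * (-2 * 0.5 / 18) = -0.5
  n <- 65L; c0 <- 33L
  xx <- matrix(seq_len(n) - c0, n, n, byrow = TRUE)
  yy <- matrix(seq_len(n) - c0, n, n)
  bump <- exp(-(xx^2 + yy^2) / (2 * 3^2))
  r <- dtg_responses(bump, 3)
  expect_equal(r$s20[c0, c0] + r$s02[c0, c0], -0.5, tolerance = 5e-3)
})

test_that("classification follows the seven-measure argmax", {
  mk <- function(s00 = 0, s10 = 0, s01 = 0, s20 = 0, s11 = 0, s02 = 0) {
    one <- function(v) matrix(v, 16, 16)
    structure(list(s00 = one(s00), s10 = one(s10), s01 = one(s01),
                   s20 = one(s20), s11 = one(s11), s02 = one(s02),
                   lambda = one(s20 + s02),
                   gamma = one(sqrt((s20 - s02)^2 + 4 * s11^2)),
                   sigma_b = 1), class = "DtgResponseSet")
  }
  # only the flatness measure is nonzero
  expect_true(all(classify_bifs(mk(s00 = 1), 0.03)$labels == 0L))
  # slope measure 2 beats flat measure 0.03
  expect_true(all(classify_bifs(mk(s00 = 1, s10 = 1), 0.03)$labels == 1L))
  # lambda = 2, gamma = 0: dark blob (2) beats dark line (1.414)
  expect_true(all(classify_bifs(mk(s20 = 1, s02 = 1), 0.03)$labels == 2L))
  # all-zero responses: tie broken towards the lowest class code (flat)
  expect_true(all(classify_bifs(mk(), 0.03)$labels == 0L))
})

test_that("per-pixel classification matches an explicit-loop oracle", {
  set.seed(11)
  for (rep in 1:3) {
    img <- matrix(runif(16 * 16, 50, 200), 16, 16)
    r <- dtg_responses(img, 1.5)
    expect_identical(classify_bifs(r, 0.03)$labels,
                     oracle_classify(r, 0.03))
  }
})

test_that("composition handles degenerate and analytic spot images", {
  expect_true(all(compute_bifs(matrix(0, 32, 32), 2)$labels == 0L))
  # dark Gaussian spot of sd 3 on a bright background, sigma_b = 3:
  # centre lambda = +0.4 > all competing measures -> dark blob
  n <- 65L; c0 <- 33L
  xx <- matrix(seq_len(n) - c0, n, n, byrow = TRUE)
  yy <- matrix(seq_len(n) - c0, n, n)
  spot <- 1 - 0.8 * exp(-(xx^2 + yy^2) / (2 * 3^2))
  b <- compute_bifs(spot, 3, 0.03)
  expect_identical(b$labels[c0, c0], 2L)
})

test_that("gamma is non-negative and bounds |s20 - s02|", {
  set.seed(5)
  img <- matrix(runif(48 * 48, 0, 100), 48, 48)
  r <- dtg_responses(img, 2)
  expect_true(all(r$gamma >= 0))
  expect_true(all(r$gamma >= abs(r$s20 - r$s02) - 1e-12))
})

test_that("lambda convention switch halves the Laplacian term", {
  set.seed(6)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_equal(dtg_responses(img, 2, "mean")$lambda,
               dtg_responses(img, 2, "sum")$lambda / 2)
})

test_that("invalid inputs are rejected", {
  expect_error(dtg_responses(matrix(1, 32, 32), -1), "sigma_b")
  expect_error(dtg_responses(matrix(1, 8, 8), 1), "16 x 16")
  expect_error(dtg_responses(matrix(c(NA, rep(1, 32 * 32 - 1)), 32), 1),
               "finite")
  r <- dtg_responses(matrix(1, 32, 32), 1)
  expect_error(classify_bifs(r, -0.1), "epsilon")
})

test_that("rendering is a bijection on labels", {
  set.seed(8)
  lab <- matrix(sample(0:6, 40 * 40, replace = TRUE), 40, 40)
  b <- structure(list(labels = lab, sigma_b = 1), class = "BifImage")
  rgb <- render_bifs(b)
  expect_identical(unrender_bifs(rgb), lab)
  cols <- unique(paste(rgb[, , 1], rgb[, , 2], rgb[, , 3]))
  expect_length(cols, 7L)   # all 7 classes present -> 7 distinct colours
  flat <- structure(list(labels = matrix(0L, 4, 4), sigma_b = 1),
                    class = "BifImage")
  frgb <- render_bifs(flat)
  expect_equal(length(unique(as.vector(frgb))), 3L)  # one colour (3 chans)
})
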