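# Pixel sampling, forest training, prediction, serialisation.

make_pair <- function(seed) {
  g <- generate_pcm_image(tiny_spec(seed = seed))
  list(image = g$image, mask = g$mask)
}

test_that("pixel sampling is uniform, reproducible and provenance-tagged", {
  p1 <- make_pair(21); p2 <- make_pair(22)
  cfg <- feature_config(scales = 1, window = 5L)
  s <- sample_training_pixels(list(p1$image, p2$image),
                              list(p1$mask, p2$mask), cfg,
                              n = 50, seed = 3)
  expect_identical(nrow(s$features), 50L)
  expect_true(all(s$provenance$image %in% 1:2))
  expect_setequal(unique(s$labels), c(0L, 1L))
  s2 <- sample_training_pixels(list(p1$image, p2$image),
                               list(p1$mask, p2$mask), cfg,
                               n = 50, seed = 3)
  expect_identical(s$features, s2$features)
  expect_identical(s$provenance, s2$provenance)
  # n larger than the pool: use everything and record it
  sall <- sample_training_pixels(list(p1$image), list(p1$mask), cfg,
                                 n = 10 * length(p1$mask), seed = 3)
  expect_true(sall$exhausted)
  expect_identical(nrow(sall$features), length(p1$mask))
  # single-class pool is untrainable
  expect_error(sample_training_pixels(list(p1$image),
                                      list(p1$mask * 0L), cfg,
                                      n = 50, seed = 3), "single class")
  # protocol default
  expect_identical(eval(formals(sample_training_pixels)$n), 50000L)
})

test_that("a separable sample trains to perfect training accuracy", {
  set.seed(30)
  x <- rbind(matrix(rnorm(200, 0), 100, 2),
             matrix(rnorm(200, 8), 100, 2))
  colnames(x) <- c("f1", "f2")
  s <- structure(list(features = x, labels = rep(0:1, each = 100),
                      provenance = NULL, seed = 1, exhausted = FALSE,
                      config = feature_config()),
                 class = "TrainingSample")
  m <- train_forest(s, n_trees = 20, seed = 4)
  pr <- predict(m$forest, data = data.frame(x), num.threads = 1)
  expect_identical(as.integer(as.character(pr$predictions)),
                   rep(0:1, each = 100))
  expect_identical(m$n_trees, 20L)
  expect_error(train_forest(s, mtry = 10), "mtry")
})

test_that("majority vote requires a strict majority; ties go background", {
  votes <- rbind(rep(1L, 20),                      # unanimous foreground
                 c(rep(1L, 10), rep(0L, 10)),      # 10-10 tie
                 c(rep(1L, 11), rep(0L, 9)))       # 11-9
  expect_identical(majority_vote(votes, 20), c(1L, 0L, 1L))
})

test_that("prediction is binary, reproducible and round-trips a model file", {
  pairs <- lapply(31:33, make_pair)
  cfg <- feature_config(scales = c(1, 2), window = 7L)
  s <- sample_training_pixels(lapply(pairs, `[[`, "image"),
                              lapply(pairs, `[[`, "mask"), cfg,
                              n = 800, seed = 5)
  m <- train_forest(s, n_trees = 10, seed = 6)
  probe <- make_pair(34)
  mask1 <- predict_mask(m, probe$image)
  expect_true(all(mask1 %in% c(0L, 1L)))
  expect_identical(dim(mask1), dim(probe$image))

  path <- tempfile(fileext = ".rds")
  save_forest(m, path)
  m2 <- load_forest(path)
  expect_identical(predict_mask(m2, probe$image), mask1)

  # same sampling + training seeds -> identical masks end to end
  s2 <- sample_training_pixels(lapply(pairs, `[[`, "image"),
                               lapply(pairs, `[[`, "mask"), cfg,
                               n = 800, seed = 5)
  m3 <- train_forest(s2, n_trees = 10, seed = 6)
  expect_identical(predict_mask(m3, probe$image), mask1)

  # version-stamped serialisation refuses foreign files
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_forest(bad), "version")
  stale <- m; stale$format_version <- "bifseg-model-0"
  saveRDS(stale, bad)
  expect_error(load_forest(bad), "version")
})
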