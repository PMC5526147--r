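# Random-forest pixel classifier: train on sampled pixel feature vectors,
# predict binary masks by majority vote across trees. The raw vote is the
# segmentation -- no morphological post-processing of any kind.

MODEL_FORMAT_VERSION <- "bifseg-model-1"

#' Sample labelled training pixels across images
#'
#' Pixels are pooled across all provided images and sampled uniformly at
#' random without replacement. If `n` exceeds the pool, all pixels are
#' used (recorded in the result). In the rare event that a uniform draw
#' misses one of the two classes, one pixel of the missing class is
#' swapped in so the sample is always trainable.
#'
#' @param images list of numeric intensity matrices.
#' @param masks list of binary matrices (1 = class of interest) aligned
#'   with `images`.
#' @param config a [feature_config()] describing the feature vectors.
#' @param n number of pixels to sample (default 50000).
#' @param seed RNG seed for reproducibility.
#' @param stratified if `TRUE`, sample `n/2` pixels per class (balanced);
#'   default `FALSE`, plain uniform sampling.
#' @return an object of class `TrainingSample`: list with `features`
#'   (n x F), `labels` (0/1), `provenance` (data.frame image, pixel),
#'   `seed`, `exhausted`.
#' @export
sample_training_pixels <- function(images, masks, config, n = 50000L,
                                   seed = NULL, stratified = FALSE) {
  stopifnot(length(images) >= 1, length(images) == length(masks), n >= 2)
  feats <- lapply(images, assemble_features, config = config)
  pool_x <- do.call(rbind, lapply(feats, `[[`, "vectors"))
  pool_y <- unlist(lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    stopifnot(identical(dim(m), feats[[i]]$source_shape))
    as.integer(as.vector(m) > 0)
  }))
  prov <- data.frame(
    image = rep(seq_along(images), vapply(feats, function(f)
      as.integer(prod(f$source_shape)), integer(1))),
    pixel = unlist(lapply(feats, function(f)
      seq_len(prod(f$source_shape))))
  )
  if (length(unique(pool_y)) < 2L)
    stop("pixel pool contains a single class; cannot train a classifier")
  if (!is.null(seed)) set.seed(seed)
  avail <- length(pool_y)
  exhausted <- n >= avail
  idx <- if (exhausted) {
    seq_len(avail)
  } else if (stratified) {
    i1 <- which(pool_y == 1L); i0 <- which(pool_y == 0L)
    c(sample(i1, min(ceiling(n / 2), length(i1))),
      sample(i0, min(floor(n / 2), length(i0))))
  } else {
    sample.int(avail, n)
  }
  y <- pool_y[idx]
  for (cls in 0:1) {
    if (!any(y == cls)) {
      cand <- which(pool_y == cls)
      idx[1L] <- cand[sample.int(length(cand), 1L)]
      y <- pool_y[idx]
    }
  }
  structure(list(features = pool_x[idx, , drop = FALSE], labels = y,
                 provenance = prov[idx, ], seed = seed,
                 exhausted = exhausted, config = config),
            class = "TrainingSample")
}

#' Train a random forest on a pixel sample
#'
#' Bagged, fully grown classification trees (no depth cap, minimum node
#' size 1) with `mtry` candidate features per split.
#'
#' @param sample a `TrainingSample` from [sample_training_pixels()].
#' @param n_trees number of trees (default 20; more gives only marginal
#'   gains at a steep cost in time and memory for pixel classification).
#' @param mtry candidate features per split; default `floor(sqrt(F))`.
#' @param seed RNG seed; fixed seed gives a deterministic model.
#' @param min_node_size minimum terminal node size (default 1).
#' @return an object of class `ForestModel` wrapping the fitted ensemble
#'   together with the feature configuration and column names used.
#' @export
train_forest <- function(sample, n_trees = 20L, mtry = NULL, seed = NULL,
                         min_node_size = 1L) {
  stopifnot(inherits(sample, "TrainingSample"), n_trees >= 1)
  f <- ncol(sample$features)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(f)))
  if (mtry > f) stop("'mtry' (", mtry, ") exceeds feature dimension ", f)
  dat <- data.frame(sample$features, check.names = FALSE)
  dat$.y <- factor(sample$labels, levels = c(0L, 1L))
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = n_trees, mtry = mtry, min.node.size = min_node_size,
    seed = seed, num.threads = 1L, respect.unordered.factors = FALSE,
    verbose = FALSE
  )
  structure(list(forest = fit, n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry),
                 feature_names = colnames(sample$features),
                 config = sample$config,
                 format_version = MODEL_FORMAT_VERSION),
            class = "ForestModel")
}

#' Predict a binary segmentation mask
#'
#' Assembles features for the image with the model's stored
#' configuration and takes the majority vote across trees at each pixel:
#' label 1 iff strictly more than half the trees vote foreground, so an
#' exact tie with an even tree count yields background (conservative,
#' deterministic). The vote is used as is; no post-processing.
#'
#' @param model a `ForestModel`.
#' @param image numeric intensity matrix.
#' @return integer matrix of 0/1 labels, same shape as `image`.
#' @export
predict_mask <- function(model, image) {
  stopifnot(inherits(model, "ForestModel"))
  fm <- assemble_features(image, model$config)
  predict_mask_features(model, fm)
}

#' Majority vote over per-tree labels
#'
#' Label 1 iff strictly more than half the trees vote 1; an exact tie
#' with an even tree count yields 0 (conservative foreground calls).
#'
#' @param tree_labels matrix of 0/1 votes, pixels x trees.
#' @param n_trees number of trees voting.
#' @return integer vector of 0/1 labels.
#' @export
majority_vote <- function(tree_labels, n_trees = ncol(tree_labels)) {
  as.integer(rowSums(tree_labels == 1L) > n_trees / 2)
}

# Map ranger per-tree prediction codes back to 0/1 labels. For
# classification forests predict.all returns per-tree factor-level
# indices; fit$forest$levels translates them back to label strings.
tree_vote_labels <- function(fit, votes) {
  as.integer(fit$forest$levels[as.vector(votes)])
}

#' Save / load a forest model
#'
#' Single-file serialisation of the ensemble, its feature configuration
#' and column names, stamped with a format-version string; loading
#' refuses a file with a different version.
#'
#' @param model a `ForestModel`.
#' @param path file path.
#' @return `load_forest` returns the `ForestModel`; `save_forest` its
#'   path, invisibly.
#' @export
save_forest <- function(model, path) {
  stopifnot(inherits(model, "ForestModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ForestModel") ||
      !identical(model$format_version, MODEL_FORMAT_VERSION))
    stop("model file format version mismatch; refusing to load")
  model
}
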