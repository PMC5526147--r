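# Segmentation scoring (F-score / Dice), confusion maps, leave-one-out
# cross-validation and parameter sweeps over window diameter and scale
# combinations.

#' Pixel-wise F-score (Dice coefficient)
#'
#' `2 * TP / (2 * TP + FP + FN)`; defined as 1 when both masks are empty
#' (perfect agreement on absence). Symmetric in its arguments.
#'
#' @param pred,truth binary matrices of identical shape (non-zero =
#'   foreground).
#' @return a number in `[0, 1]`.
#' @export
f_score <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  if (cc[["tp"]] + cc[["fp"]] + cc[["fn"]] == 0) return(1)
  2 * cc[["tp"]] / (2 * cc[["tp"]] + cc[["fp"]] + cc[["fn"]])
}

#' Confusion counts between two binary masks
#'
#' @inheritParams f_score
#' @return named numeric vector `tp, fp, tn, fn`; the four counts sum to
#'   the number of pixels.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("'pred' and 'truth' must have identical shapes")
  p <- as.vector(pred) > 0; t <- as.vector(truth) > 0
  c(tp = sum(p & t), fp = sum(p & !t), tn = sum(!p & !t), fn = sum(!p & t))
}

#' Per-pixel confusion map
#'
#' @inheritParams f_score
#' @return character matrix with entries `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @export
confusion_map <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("'pred' and 'truth' must have identical shapes")
  p <- pred > 0; t <- truth > 0
  out <- matrix("TN", nrow(pred), ncol(pred))
  out[p & t] <- "TP"; out[p & !t] <- "FP"; out[!p & t] <- "FN"
  out
}

#' Leave-one-out cross-validation of the segmentation pipeline
#'
#' For each of the N images, a forest is trained on `n_samples` pixels
#' sampled across the other N - 1 images and used to predict every pixel
#' of the left-out image; agreement with ground truth is scored with the
#' F-score. Per-round seeds are spawned deterministically from the master
#' seed so each round is independently reproducible.
#'
#' @param images list of numeric intensity matrices (N >= 2).
#' @param truths list of ground-truth label matrices. With
#'   `target_class = 1` (default) these are binary masks; for multi-class
#'   truths the target class is foreground and everything else background.
#' @param config a [feature_config()].
#' @param n_trees,mtry forest parameters (see [train_forest()]).
#' @param n_samples training pixels per round (default 50000).
#' @param seed master seed.
#' @param target_class label value treated as foreground.
#' @return an object of class `EvalReport`: list with `per_image_scores`,
#'   `mean`, `sd` (sample standard deviation over images), total
#'   confusion counts `tp, fp, tn, fn`, aggregate `f_score`, and the
#'   predicted masks.
#' @export
loocv <- function(images, truths, config, n_trees = 20L, mtry = NULL,
                  n_samples = 50000L, seed = 1L, target_class = 1L) {
  n <- length(images)
  stopifnot(n >= 2, length(truths) == n)
  masks <- lapply(truths, function(t) (t == target_class) * 1L)
  feats <- lapply(images, assemble_features, config = config)
  seeds <- spawn_seeds(seed, 2L * n)
  scores <- numeric(n)
  counts <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    hold <- tryCatch({
      tr <- pooled_sample(feats[-i], masks[-i], config, n_samples,
                          seeds[2L * i - 1L])
      model <- train_forest(tr, n_trees = n_trees, mtry = mtry,
                            seed = seeds[2L * i])
      predict_mask_features(model, feats[[i]])
    }, error = function(e)
      stop("LOOCV round ", i, " failed: ", conditionMessage(e)))
    preds[[i]] <- hold
    scores[i] <- f_score(hold, masks[[i]])
    counts <- counts + confusion_counts(hold, masks[[i]])
  }
  agg <- if (sum(counts[c("tp", "fp", "fn")]) == 0) 1 else
    2 * counts[["tp"]] / (2 * counts[["tp"]] + counts[["fp"]] +
                            counts[["fn"]])
  structure(list(per_image_scores = scores, mean = mean(scores),
                 sd = stats::sd(scores), tp = counts[["tp"]],
                 fp = counts[["fp"]], tn = counts[["tn"]],
                 fn = counts[["fn"]], f_score = agg,
                 predictions = preds, config = config, seed = seed),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("LOOCV over %d images: F = %.3f +/- %.3f\n",
              length(x$per_image_scores), x$mean, x$sd))
  cat(sprintf("  per image: %s\n",
              paste(sprintf("%.3f", x$per_image_scores), collapse = " ")))
  invisible(x)
}

#' Sweep window diameters and scale combinations
#'
#' Runs [loocv()] once per (window, scale set) cell and tabulates mean and
#' standard deviation of the per-image F-scores. A window of 1 pixel is
#' the single-value-per-scale baseline. One master seed spawns per-cell
#' seeds deterministically, so any cell can be recomputed on its own.
#'
#' @param images,truths as in [loocv()].
#' @param windows integer vector of window diameters (1 allowed).
#' @param scale_sets list of scale vectors, e.g.
#'   `list(1, c(1, 2), c(1, 2, 4))`.
#' @param config_base a [feature_config()] supplying all non-swept
#'   settings.
#' @param ... forwarded to [loocv()] (`n_trees`, `n_samples`,
#'   `target_class`, ...).
#' @param seed master seed.
#' @return data.frame with columns `window`, `scales`, `mean_f`, `sd_f`
#'   and one `f_img<i>` column per image.
#' @export
parameter_sweep <- function(images, truths, windows, scale_sets,
                            config_base = feature_config(), ...,
                            seed = 1L) {
  stopifnot(length(windows) >= 1, length(scale_sets) >= 1)
  cells <- expand.grid(wi = seq_along(windows),
                       si = seq_along(scale_sets))
  seeds <- spawn_seeds(seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    w <- windows[cells$wi[ci]]; sc <- scale_sets[[cells$si[ci]]]
    cfg <- config_base
    cfg$window <- as.integer(w); cfg$scales <- as.numeric(sc)
    rep <- loocv(images, truths, cfg, ..., seed = seeds[ci])
    out <- data.frame(window = w,
                      scales = paste(sc, collapse = "+"),
                      mean_f = rep$mean, sd_f = rep$sd)
    for (i in seq_along(rep$per_image_scores))
      out[[sprintf("f_img%d", i)]] <- rep$per_image_scores[i]
    out
  })
  do.call(rbind, rows)
}

# Spawn n reproducible sub-seeds (< 2^31) from one master seed.
spawn_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Train-time helper: sample from precomputed per-image feature matrices
# (avoids recomputing features every LOOCV round).
pooled_sample <- function(feats, masks, config, n, seed) {
  pool_x <- do.call(rbind, lapply(feats, `[[`, "vectors"))
  pool_y <- unlist(lapply(seq_along(masks), function(i)
    as.integer(as.vector(masks[[i]]) > 0)))
  if (length(unique(pool_y)) < 2L)
    stop("pixel pool contains a single class; cannot train a classifier")
  set.seed(seed)
  avail <- length(pool_y)
  idx <- if (n >= avail) seq_len(avail) else sample.int(avail, n)
  y <- pool_y[idx]
  for (cls in 0:1) {
    if (!any(y == cls)) {
      cand <- which(pool_y == cls)
      idx[1L] <- cand[sample.int(length(cand), 1L)]
      y <- pool_y[idx]
    }
  }
  structure(list(features = pool_x[idx, , drop = FALSE], labels = y,
                 provenance = NULL, seed = seed, exhausted = n >= avail,
                 config = config),
            class = "TrainingSample")
}

# Predict from a precomputed FeatureMatrix (internal fast path).
predict_mask_features <- function(model, fm) {
  if (!identical(fm$feature_names, model$feature_names))
    stop("feature layout does not match the model's configuration")
  dat <- data.frame(fm$vectors, check.names = FALSE)
  pr <- stats::predict(model$forest, data = dat, predict.all = TRUE,
                       num.threads = 1L, verbose = FALSE)
  lab <- matrix(tree_vote_labels(model$forest, pr$predictions),
                nrow(pr$predictions))
  matrix(majority_vote(lab, model$n_trees),
         fm$source_shape[1], fm$source_shape[2])
}
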