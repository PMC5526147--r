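# Per-pixel feature vectors: local histograms of BIF classes and of
# quantised intensity / normalised-contrast values, concatenated across
# scales in a fixed (channel, scale, bin) order.

#' Feature configuration
#'
#' @param scales strictly increasing positive filter scales (sigma_B, in
#'   pixels) at which features are computed; the usual progression is
#'   subsets of `c(1, 2, 4, 8, 16)`.
#' @param window window diameter `w` of the local histogram in pixels
#'   (integer >= 1); `w = 1` is the single-value-per-scale baseline in
#'   which each scale contributes its raw label instead of a histogram.
#' @param channels subset of `c("bifs", "intensity", "contrast")`.
#' @param epsilon BIF flatness threshold (default 0.03).
#' @param intensity_bins,contrast_bins histogram bins for the intensity
#'   and contrast channels (default 10 each; BIFs always have 7).
#' @param lambda_convention,truncation passed to [compute_bifs()] and
#'   [soft_local_histograms()].
#' @return an object of class `FeatureConfig`.
#' @export
feature_config <- function(scales = c(1, 2, 4), window = 15L,
                           channels = "bifs", epsilon = 0.03,
                           intensity_bins = 10L, contrast_bins = 10L,
                           lambda_convention = c("sum", "mean"),
                           truncation = c("two_sigma", "half_window")) {
  lambda_convention <- match.arg(lambda_convention)
  truncation <- match.arg(truncation)
  stopifnot(length(scales) >= 1, all(scales > 0),
            !is.unsorted(scales, strictly = TRUE),
            window >= 1, window == round(window),
            length(channels) >= 1,
            all(channels %in% c("bifs", "intensity", "contrast")),
            epsilon > 0, intensity_bins >= 2, contrast_bins >= 2)
  structure(list(scales = as.numeric(scales), window = as.integer(window),
                 channels = channels, epsilon = epsilon,
                 intensity_bins = as.integer(intensity_bins),
                 contrast_bins = as.integer(contrast_bins),
                 lambda_convention = lambda_convention,
                 truncation = truncation),
            class = "FeatureConfig")
}

#' Number of feature columns implied by a configuration
#'
#' `F = sum over channels and scales of bins-per-channel` (7 for BIFs, 10
#' each for intensity and contrast by default) when `window > 1`, and one
#' column per channel-scale when `window = 1`.
#'
#' @param config a `FeatureConfig`.
#' @return integer F.
#' @export
feature_dim <- function(config) {
  stopifnot(inherits(config, "FeatureConfig"))
  bins <- channel_bins(config)
  m <- length(config$scales)
  if (config$window == 1L) length(config$channels) * m
  else sum(bins[config$channels]) * m
}

channel_bins <- function(config) {
  c(bifs = 7L, intensity = config$intensity_bins,
    contrast = config$contrast_bins)
}

#' Blur and linearly quantise an image
#'
#' The image is Gaussian-blurred at `sigma` and quantised between its
#' per-image minimum and maximum into `n_bins` equal levels `0 ..
#' n_bins - 1`. A constant image maps entirely to bin 0 (degenerate range).
#' The per-image range is used (rather than a global one) because PCM
#' illumination varies between images.
#'
#' @param image numeric intensity matrix.
#' @param sigma blur scale in pixels, > 0.
#' @param n_bins number of quantisation levels, >= 2.
#' @return integer matrix with values in `0 .. n_bins - 1`.
#' @export
quantize_intensity <- function(image, sigma, n_bins = 10L) {
  stopifnot(sigma > 0, n_bins >= 2)
  image <- as_gray_image(image)
  b <- gauss_blur(image, sigma)
  rng <- range(b)
  if (rng[2] <= rng[1]) return(matrix(0L, nrow(b), ncol(b)))
  q <- floor((b - rng[1]) / (rng[2] - rng[1]) * n_bins)
  q <- pmin(q, n_bins - 1L)
  matrix(as.integer(q), nrow(b), ncol(b))
}

#' Soft-edged normalised contrast filter
#'
#' Gaussian-weighted local standard deviation divided by Gaussian-weighted
#' local mean (a soft-windowed coefficient of variation) at scale `sigma`.
#' Output is non-negative and invariant under positive rescaling of the
#' image. The denominator is offset by `.Machine$double.eps` times the
#' largest absolute local mean so an identically dark window never divides
#' by zero.
#'
#' @param image numeric intensity matrix.
#' @param sigma window scale (standard deviation) in pixels, > 0.
#' @return non-negative numeric matrix.
#' @export
contrast_filter <- function(image, sigma) {
  stopifnot(sigma > 0)
  image <- as_gray_image(image)
  m1 <- gauss_blur(image, sigma)
  m2 <- gauss_blur(image^2, sigma)
  v <- pmax(m2 - m1^2, 0)
  off <- .Machine$double.eps * max(abs(m1), 1)
  sqrt(v) / (abs(m1) + off)
}

#' Assemble the per-pixel feature matrix
#'
#' For each channel and each scale, computes the per-pixel label image
#' (BIF class, intensity bin, or contrast bin), takes soft local
#' histograms at the configured window, and concatenates the bins per
#' pixel in fixed (channel, scale, bin) order: channels in the order
#' bifs, intensity, contrast; scales ascending; bins ascending. With
#' `window = 1` each channel-scale contributes its raw label value as a
#' single column (the single-value baseline). Deterministic: identical
#' input and configuration yield an identical matrix.
#'
#' @param image numeric intensity matrix.
#' @param config a [feature_config()].
#' @return an object of class `FeatureMatrix`: list with `vectors`
#'   (P x F matrix, pixels in R column-major raster order), `feature_names`
#'   (length F, "channel.s<scale>.<bin>" provenance) and `source_shape`.
#' @export
assemble_features <- function(image, config) {
  stopifnot(inherits(config, "FeatureConfig"))
  image <- as_gray_image(image)
  shp <- dim(image)
  p <- prod(shp)
  ord <- c("bifs", "intensity", "contrast")
  chans <- ord[ord %in% config$channels]
  bins <- channel_bins(config)
  cols <- list(); nms <- character(0)
  for (ch in chans) {
    for (s in config$scales) {
      lab <- switch(ch,
        bifs = compute_bifs(image, s, config$epsilon,
                            config$lambda_convention)$labels,
        intensity = quantize_intensity(image, s, config$intensity_bins),
        contrast = quantize_contrast(image, s, config$contrast_bins)
      )
      if (config$window == 1L) {
        cols[[length(cols) + 1L]] <- matrix(as.numeric(lab), p, 1L)
        nms <- c(nms, sprintf("%s.s%g.value", ch, s))
      } else {
        h <- soft_local_histograms(lab, bins[[ch]], config$window,
                                   config$truncation)
        cols[[length(cols) + 1L]] <- matrix(h$bins, p, bins[[ch]])
        nms <- c(nms, sprintf("%s.s%g.b%02d", ch, s, seq_len(bins[[ch]])))
      }
    }
  }
  v <- do.call(cbind, cols)
  colnames(v) <- nms
  stopifnot(ncol(v) == feature_dim(config), all(is.finite(v)))
  structure(list(vectors = v, feature_names = nms, source_shape = shp),
            class = "FeatureMatrix")
}

# Contrast channel labels: contrast map quantised by the same per-image
# min-max rule as intensity (without further blurring).
quantize_contrast <- function(image, sigma, n_bins) {
  cmap <- contrast_filter(image, sigma)
  rng <- range(cmap)
  if (rng[2] <= rng[1]) return(matrix(0L, nrow(cmap), ncol(cmap)))
  q <- pmin(floor((cmap - rng[1]) / (rng[2] - rng[1]) * n_bins), n_bins - 1L)
  matrix(as.integer(q), nrow(cmap), ncol(cmap))
}
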