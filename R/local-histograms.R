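# Soft-edged local histograms of a label image, computed by convolving
# per-class indicator masks with a normalised Gaussian window. The result
# is a locally orderless representation: per-pixel class statistics with
# the spatial arrangement inside the window discarded.

#' Per-class binary indicator masks of a label image
#'
#' @param labels integer matrix with values in `0 .. n_classes - 1`.
#' @param n_classes number of classes K.
#' @return an object of class `MaskStack`: a 3-D array
#'   `rows x cols x K` of 0/1 indicators; the K planes partition the
#'   image (they sum to 1 at every pixel).
#' @export
binary_masks <- function(labels, n_classes) {
  stopifnot(is.matrix(labels), n_classes >= 1)
  if (any(labels < 0L | labels >= n_classes))
    stop("labels outside 0..", n_classes - 1L)
  m <- array(0, c(nrow(labels), ncol(labels), n_classes))
  for (k in seq_len(n_classes)) m[, , k] <- (labels == k - 1L) * 1
  structure(m, class = c("MaskStack", class(m)))
}

#' Soft-edged local histograms by Gaussian-window convolution
#'
#' Each of the K class-indicator masks is filtered with a normalised 2-D
#' Gaussian of standard deviation `sigma_w = w / 2`, where `w` is the
#' nominal window diameter in pixels. The per-pixel histogram is the
#' K-vector of filtered indicator values; because the kernel sums to one
#' and the masks partition the image (and boundaries are reflected), the
#' histograms sum to unity at every pixel. `w = 1` degenerates to the
#' one-hot label indicator.
#'
#' @param labels integer matrix with values in `0 .. n_classes - 1`.
#' @param n_classes number of histogram bins K.
#' @param w window diameter in pixels (integer >= 1).
#' @param truncation `"two_sigma"` (default): kernel truncated at radius
#'   `ceiling(2 * sigma_w)` = `w`, retaining >= 95% of the Gaussian mass so
#'   the nominal diameter is the effective support; `"half_window"`:
#'   literal truncation at radius `ceiling(w / 2)` (1 sigma), for fidelity
#'   experiments. The kernel is renormalised to unit sum either way.
#' @return an object of class `SoftHistogramField`: list with `bins`
#'   (array `rows x cols x K`, values in `[0, 1]`, unit-sum per pixel),
#'   `w`, `sigma_w` and `n_bins`.
#' @export
soft_local_histograms <- function(labels, n_classes, w,
                                  truncation = c("two_sigma",
                                                 "half_window")) {
  truncation <- match.arg(truncation)
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w != round(w))
    stop("'w' must be a single integer >= 1")
  masks <- binary_masks(labels, n_classes)
  sigma_w <- w / 2
  bins <- array(0, dim(masks))
  if (w == 1) {
    bins[] <- masks
  } else {
    radius <- if (truncation == "two_sigma") ceiling(2 * sigma_w)
              else max(1L, ceiling(w / 2))
    k <- gaussian_kernel(sigma_w, 0L, radius)
    for (kk in seq_len(n_classes))
      bins[, , kk] <- filter_separable(masks[, , kk], k, k)
  }
  structure(list(bins = bins, w = as.integer(w), sigma_w = sigma_w,
                 n_bins = as.integer(n_classes)),
            class = "SoftHistogramField")
}
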