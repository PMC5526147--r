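# Separable image filtering with symmetric (reflected, edge-repeated)
# boundary handling. All scale-space filtering in the package funnels
# through these helpers so truncation and padding are uniform.

#' Reflect out-of-range indices into [1, n]
#'
#' Symmetric boundary with edge repetition (…, 2, 1, 1, 2, …, n, n, n-1, …),
#' valid for arbitrarily distant indices (period 2n).
#'
#' @param i integer vector of (possibly out-of-range) indices.
#' @param n extent of the axis.
#' @return integer vector of indices in `[1, n]`.
#' @keywords internal
reflect_index <- function(i, n) {
  i0 <- (i - 1L) %% (2L * n)
  as.integer(ifelse(i0 < n, i0 + 1L, 2L * n - i0))
}

#' Sampled Gaussian (derivative) kernel
#'
#' The order-0 kernel is normalised to unit sum. Derivative kernels are
#' the Hermite-weighted forms built from the same sampled Gaussian,
#' oriented for correlation semantics, and moment-corrected so the
#' discrete filters reproduce polynomial responses exactly: derivative
#' kernels sum to zero (constants are annihilated), the order-1 kernel
#' has unit first moment (a unit ramp differentiates to exactly 1) and
#' the order-2 kernel has second moment 2 (x^2 differentiates to exactly
#' 2). Without the correction, sampling plus truncation leaves
#' relative moment errors of order 1e-3 at small sigma.
#'
#' @param sigma standard deviation in pixels (> 0).
#' @param order derivative order, 0, 1 or 2.
#' @param radius half support in pixels; default `ceiling(4 * sigma)`.
#' @return numeric vector of length `2 * radius + 1`.
#' @keywords internal
gaussian_kernel <- function(sigma, order = 0L, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0, order %in% 0:2, radius >= 1)
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- x / sigma^2 * g
    k <- k - mean(k)                 # exact zero response to constants
    k / sum(x * k)                   # exact unit response to a ramp
  } else {
    k <- (x^2 - sigma^2) / sigma^4 * g
    k <- k - mean(k)                 # symmetric, so odd moments stay 0
    2 * k / sum(x^2 * k)             # exact response 2 to x^2
  }
}

# Correlate a matrix with a 1-D kernel along one margin, symmetric padding.
filter_axis <- function(x, k, margin = c("rows", "cols")) {
  margin <- match.arg(margin)
  r <- (length(k) - 1L) %/% 2L
  n <- if (margin == "rows") nrow(x) else ncol(x)
  idx <- reflect_index(seq.int(1L - r, n + r), n)
  out <- NULL
  if (margin == "rows") {
    p <- x[idx, , drop = FALSE]
    out <- matrix(0, nrow(x), ncol(x))
    for (t in seq_along(k)) {
      out <- out + k[t] * p[seq.int(t, t + n - 1L), , drop = FALSE]
    }
  } else {
    p <- x[, idx, drop = FALSE]
    out <- matrix(0, nrow(x), ncol(x))
    for (t in seq_along(k)) {
      out <- out + k[t] * p[, seq.int(t, t + n - 1L), drop = FALSE]
    }
  }
  out
}

#' Separable correlation of an image with per-axis kernels
#'
#' Rows index y, columns index x. `kx` is applied along columns (the x
#' direction), `ky` along rows.
#'
#' @param x numeric matrix.
#' @param kx,ky 1-D kernels (odd length).
#' @return filtered matrix, same shape as `x`.
#' @keywords internal
filter_separable <- function(x, kx, ky) {
  filter_axis(filter_axis(x, ky, "rows"), kx, "cols")
}

#' Gaussian blur with symmetric boundary
#'
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels.
#' @param radius kernel half support; default `ceiling(4 * sigma)`.
#' @return blurred matrix.
#' @keywords internal
gauss_blur <- function(x, sigma, radius = ceiling(4 * sigma)) {
  k <- gaussian_kernel(sigma, 0L, radius)
  filter_separable(x, k, k)
}
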