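# Basic Image Features: seven-way classification of local image structure
# (flat, slope, dark/bright blob, dark/bright line, saddle) from
# scale-normalised derivative-of-Gaussian responses.

BIF_CLASSES <- c("flat", "slope", "dark_blob", "bright_blob",
                 "dark_line", "bright_line", "saddle")

#' Fixed colour palette for the seven BIF classes
#'
#' flat = pink, slope = grey, dark blob = black, bright blob = white,
#' dark line = blue, bright line = yellow, saddle = green.
#'
#' @return named character vector of 7 hex colours, in class-code order
#'   (codes 0 to 6).
#' @export
bif_palette <- function() {
  c(flat = "#FFC0CB", slope = "#808080", dark_blob = "#000000",
    bright_blob = "#FFFFFF", dark_line = "#0000FF",
    bright_line = "#FFFF00", saddle = "#00A000")
}

#' Scale-normalised derivative-of-Gaussian responses
#'
#' Correlates the image with Gaussian derivative kernels up to second order
#' at scale `sigma_b` and multiplies each order-(i+j) response by
#' `sigma_b^(i+j)` so responses are comparable across scales. Also returns
#' the Laplacian term `lambda` and the directional-variance term `gamma`
#' used for BIF classification.
#'
#' @param image numeric matrix (rows = y, cols = x), at least 16 x 16,
#'   finite values.
#' @param sigma_b filter scale (standard deviation) in pixels, > 0.
#' @param lambda_convention `"sum"` (default, `lambda = s20 + s02`, the
#'   convention under which the flatness threshold 0.03 was calibrated) or
#'   `"mean"` (`(s20 + s02) / 2`, the literal mean over directions).
#' @return an object of class `DtgResponseSet`: a list with matrices
#'   `s00, s10, s01, s20, s11, s02` (scale-normalised responses), `lambda`,
#'   `gamma` (always >= 0), and the scalar `sigma_b`.
#' @details Kernels are truncated at radius `ceiling(4 * sigma_b)`
#'   (truncation error < 1e-4); boundaries use symmetric reflection.
#' @export
dtg_responses <- function(image, sigma_b,
                          lambda_convention = c("sum", "mean")) {
  lambda_convention <- match.arg(lambda_convention)
  if (!is.numeric(sigma_b) || length(sigma_b) != 1L || sigma_b <= 0)
    stop("'sigma_b' must be a single positive number")
  image <- as_gray_image(image)
  if (nrow(image) < 16L || ncol(image) < 16L)
    stop("image must be at least 16 x 16 pixels")
  r <- ceiling(4 * sigma_b)
  k0 <- gaussian_kernel(sigma_b, 0L, r)
  k1 <- gaussian_kernel(sigma_b, 1L, r)
  k2 <- gaussian_kernel(sigma_b, 2L, r)
  s <- list(
    s00 = filter_separable(image, k0, k0),
    s10 = sigma_b   * filter_separable(image, k1, k0),
    s01 = sigma_b   * filter_separable(image, k0, k1),
    s20 = sigma_b^2 * filter_separable(image, k2, k0),
    s11 = sigma_b^2 * filter_separable(image, k1, k1),
    s02 = sigma_b^2 * filter_separable(image, k0, k2)
  )
  lam <- s$s20 + s$s02
  if (lambda_convention == "mean") lam <- lam / 2
  gam <- sqrt((s$s20 - s$s02)^2 + 4 * s$s11^2)
  structure(c(s, list(lambda = lam, gamma = gam, sigma_b = sigma_b,
                      lambda_convention = lambda_convention)),
            class = "DtgResponseSet")
}

#' Classify derivative responses into the seven BIF classes
#'
#' Per pixel, seven competing measures are evaluated and the class of the
#' largest wins: flat `eps * |s00|`; slope `2 * sqrt(s10^2 + s01^2)`;
#' dark blob `+lambda`; bright blob `-lambda`; dark line
#' `(gamma + lambda) / sqrt(2)`; bright line `(gamma - lambda) / sqrt(2)`;
#' saddle `gamma`. Ties are resolved by fixed priority (lowest class code
#' wins: flat > slope > dark blob > bright blob > dark line > bright line >
#' saddle), so output is deterministic. The flatness measure uses the
#' magnitude of the smoothed intensity so that class assignments are
#' invariant under intensity negation up to the dark/bright polarity swap.
#'
#' @param responses a `DtgResponseSet` from [dtg_responses()].
#' @param epsilon dimensionless flatness threshold, > 0; 0.03 works well
#'   across scales.
#' @return an object of class `BifImage`: list with integer matrix
#'   `labels` (values 0-6, see [bif_palette()] for the code order) and
#'   `sigma_b`.
#' @export
classify_bifs <- function(responses, epsilon = 0.03) {
  stopifnot(inherits(responses, "DtgResponseSet"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("'epsilon' must be a single positive number")
  shp <- dim(responses$s00)
  for (nm in c("s10", "s01", "s20", "s11", "s02"))
    if (!identical(dim(responses[[nm]]), shp))
      stop("response planes have mismatched shapes")
  lam <- responses$lambda
  gam <- responses$gamma
  m <- cbind(
    epsilon * abs(as.vector(responses$s00)),
    2 * sqrt(as.vector(responses$s10)^2 + as.vector(responses$s01)^2),
    as.vector(lam),
    -as.vector(lam),
    (as.vector(gam) + as.vector(lam)) / sqrt(2),
    (as.vector(gam) - as.vector(lam)) / sqrt(2),
    as.vector(gam)
  )
  lab <- max.col(m, ties.method = "first") - 1L
  structure(list(labels = matrix(lab, shp[1], shp[2]),
                 sigma_b = responses$sigma_b),
            class = "BifImage")
}

#' Compute the BIF image of a grayscale image at one scale
#'
#' Composition of [dtg_responses()] and [classify_bifs()]; deterministic.
#' Class labels are invariant under positive rescaling of the image (all
#' seven measures scale linearly), equivariant under axis-aligned rotations
#' and flips, and swap dark/bright polarity under negation.
#'
#' @inheritParams dtg_responses
#' @inheritParams classify_bifs
#' @return a `BifImage`.
#' @export
compute_bifs <- function(image, sigma_b, epsilon = 0.03,
                         lambda_convention = c("sum", "mean")) {
  classify_bifs(dtg_responses(image, sigma_b, lambda_convention), epsilon)
}

#' Render a BIF image to RGB
#'
#' Maps each class to its fixed palette colour ([bif_palette()]). The
#' mapping is a bijection, so labels can be recovered from the rendering.
#'
#' @param bifs a `BifImage`.
#' @return numeric array `rows x cols x 3` with values in `[0, 1]`.
#' @export
render_bifs <- function(bifs) {
  stopifnot(inherits(bifs, "BifImage"))
  lab <- bifs$labels
  if (any(lab < 0L | lab > 6L)) stop("BIF labels must lie in 0..6")
  pal <- grDevices::col2rgb(bif_palette()) / 255
  rgb <- array(0, c(nrow(lab), ncol(lab), 3L))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[ch, lab + 1L], nrow(lab))
  rgb
}

#' Recover BIF labels from a rendering
#'
#' Inverse of [render_bifs()].
#'
#' @param rgb numeric array `rows x cols x 3` produced by [render_bifs()].
#' @return integer matrix of labels 0-6.
#' @export
unrender_bifs <- function(rgb) {
  pal <- grDevices::col2rgb(bif_palette()) / 255
  key <- apply(pal, 2, paste, collapse = "/")
  px <- paste(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
              as.vector(rgb[, , 3]), sep = "/")
  lab <- match(px, key) - 1L
  if (anyNA(lab)) stop("rendering contains colours outside the BIF palette")
  matrix(lab, dim(rgb)[1], dim(rgb)[2])
}

# Coerce to a validated numeric matrix of intensities.
as_gray_image <- function(image) {
  if (inherits(image, "GrayImage")) return(image)
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix (single-channel)")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  storage.mode(image) <- "double"
  image
}
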