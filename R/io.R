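# Image, mask and report file handling. Images are read as single-channel
# float matrices on a [0, 1] scale; BIF labels are invariant under
# positive intensity rescaling, so the native bit depth only matters for
# provenance and is kept as an attribute.

#' Read a grayscale image (TIFF or PNG)
#'
#' 8- and 16-bit images are converted to float on a `[0, 1]` scale.
#' Multi-channel files are accepted only if all colour channels are equal
#' (i.e. gray stored as RGB); an alpha channel is ignored.
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @return numeric matrix with attribute `bit_depth_origin`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, info = FALSE),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3]
    ch <- if (nch >= 3L) 3L else 1L   # colour channels before alpha
    for (k in seq_len(ch))
      if (max(abs(px[, , k] - px[, , 1])) > 1e-6)
        stop("image is not grayscale: colour channels differ")
    px <- px[, , 1]
  }
  if (!is.matrix(px)) stop("could not read a 2-D image from ", path)
  attr(px, "bit_depth_origin") <- if (ext == "png") "png" else "tiff"
  px
}

#' Write / read a binary mask as 8-bit PNG
#'
#' Convention: foreground = 255, background = 0; reading binarises at
#' > 127.
#'
#' @param mask 0/1 matrix.
#' @param path file path.
#' @return `read_mask_png` returns a 0/1 integer matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  matrix(as.integer(px > 127 / 255), nrow(px), ncol(px))
}

#' Write a BIF label image as an 8-bit single-channel PNG
#'
#' Labels 0-6 are stored as gray levels 0-6 (read back with
#' [read_label_png()]).
#'
#' @param labels integer matrix of labels 0-6 (or a `BifImage`).
#' @param path file path.
#' @export
write_label_png <- function(labels, path) {
  if (inherits(labels, "BifImage")) labels <- labels$labels
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
}

#' Write an RGB array as PNG
#'
#' @param rgb `rows x cols x 3` array in `[0, 1]`.
#' @param path file path.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write a confusion map as an RGB PNG
#'
#' TP green, FP red, FN blue, TN black.
#'
#' @param cmap character matrix from [confusion_map()].
#' @param path file path.
#' @export
write_confusion_png <- function(cmap, path) {
  rgb <- array(0, c(nrow(cmap), ncol(cmap), 3L))
  rgb[, , 1][cmap == "FP"] <- 1
  rgb[, , 2][cmap == "TP"] <- 1
  rgb[, , 3][cmap == "FN"] <- 1
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write a normalised grayscale image as 16-bit TIFF
#'
#' Intensities are rescaled to `[0, 1]` by the per-image min/max before
#' writing (labels computed from the image are invariant under this).
#'
#' @param image numeric matrix.
#' @param path file path.
#' @export
write_image_tiff <- function(image, path) {
  rng <- range(image)
  z <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
       else image * 0
  tiff::writeTIFF(z, path, bits.per.sample = 16L)
  invisible(path)
}

#' Tabulate an evaluation report as a data.frame
#'
#' @param report an `EvalReport` from [loocv()].
#' @return data.frame with one row per image plus the aggregate counts as
#'   attributes-free columns `mean_f`, `sd_f` repeated for convenience.
#' @export
eval_report_df <- function(report) {
  stopifnot(inherits(report, "EvalReport"))
  data.frame(image = seq_along(report$per_image_scores),
             f = report$per_image_scores,
             mean_f = report$mean, sd_f = report$sd)
}
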