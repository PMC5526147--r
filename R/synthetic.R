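# Synthetic phase-contrast microscopy images with exact ground truth.
# The generator reproduces the statistical structure that makes PCM
# segmentation hard: shade-off (object interiors nearly as bright as the
# background), bright halo rims just outside object boundaries, smooth
# illumination gradients, and correlated background granularity. Halos
# are artefacts, not cells, so they are excluded from the foreground
# mask.

#' Specification of a synthetic PCM image
#'
#' Defaults emulate a low-contrast stem-cell colony field on a 128 x 128
#' crop: three colonies of radius 14-26 px, background level 100
#' intensity units, shade-off ratio 0.95 (interiors only 5% dimmer than
#' background), a bright halo of amplitude 25 and decay width 4 px
#' hugging each object (halos are routinely the brightest structures in
#' PCM), a smooth illumination gradient of amplitude 10 across the field,
#' and fine-grained sensor-like background noise (sd 3, grain 1 px).
#' Foreground interiors carry coarse granular texture (sd 10, grain 2 px,
#' the organelle-scale granularity of cells) so objects are separable by
#' local structure even though shade-off removes most of the
#' mean-intensity contrast.
#'
#' @param shape image size `c(rows, cols)`, at least 64 x 64.
#' @param n_objects number of non-overlapping objects.
#' @param radius_range object radius range in pixels (radii >= 2).
#' @param halo_amplitude additive halo brightness (intensity units).
#' @param halo_width halo decay length in pixels.
#' @param shade_off interior-to-background intensity ratio in `[0, 1]`;
#'   1 means interiors match the background in mean intensity.
#' @param background_level base background intensity.
#' @param gradient_amplitude peak-to-trough illumination gradient.
#' @param noise_sd,noise_grain background noise standard deviation and
#'   correlation (grain) scale in pixels.
#' @param texture_sd,texture_grain foreground interior texture sd and
#'   grain scale.
#' @param texture_b_grain,texture_b_aspect granularity and elongation of
#'   the second foreground class for [generate_cocultured_image()]:
#'   class B texture is correlated noise of grain `texture_b_grain`
#'   stretched by `texture_b_aspect` along a random orientation
#'   (fibroblast-like streaks).
#' @param granule_density,granule_sd,granule_amplitude sparse-granule
#'   texture of class A in [generate_cocultured_image()]: granules per
#'   pixel squared, granule radius (Gaussian sd, px) and peak amplitude.
#'   Granules take random sign so the class-A mean stays matched to
#'   class B. The default density (about 1 per 17 x 17 px) makes class-A
#'   interiors locally quiet -- a small histogram window frequently
#'   contains no granule and then resembles plain background, so
#'   reliable discrimination needs a window comparable to the granule
#'   spacing.
#' @param seed RNG seed; a fixed seed gives a bit-identical image/mask
#'   pair.
#' @return an object of class `SyntheticSpec` (a validated list).
#' @export
synthetic_spec <- function(shape = c(128L, 128L), n_objects = 3L,
                           radius_range = c(14, 26),
                           halo_amplitude = 25, halo_width = 4,
                           shade_off = 0.95, background_level = 100,
                           gradient_amplitude = 10,
                           noise_sd = 3, noise_grain = 1,
                           texture_sd = 10, texture_grain = 2,
                           texture_b_grain = 1.2, texture_b_aspect = 4,
                           granule_density = 1 / 300, granule_sd = 2,
                           granule_amplitude = 25, seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 64),
            n_objects >= 1, all(radius_range >= 2),
            radius_range[1] <= radius_range[2],
            shade_off >= 0, shade_off <= 1,
            all(is.finite(c(halo_amplitude, halo_width, noise_sd,
                            gradient_amplitude, texture_sd))))
  structure(as.list(environment()), class = "SyntheticSpec")
}

# Correlated zero-mean noise field: white Gaussian noise blurred at the
# grain scale and rescaled to the requested sd.
grain_field <- function(shape, sd, grain) {
  if (sd <= 0) return(matrix(0, shape[1], shape[2]))
  z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  if (grain > 0) z <- gauss_blur(z, grain)
  z <- z - mean(z)
  z * (sd / stats::sd(as.vector(z)))
}

# Sparse granule field: Poisson-scattered Gaussian bumps of random sign
# (zero mean by construction in expectation).
granule_field <- function(shape, density, gsd, amplitude) {
  n <- stats::rpois(1, density * prod(shape))
  z <- matrix(0, shape[1], shape[2])
  if (n == 0) return(z)
  ys <- stats::runif(n, 1, shape[1]); xs <- stats::runif(n, 1, shape[2])
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  z[cbind(pmin(pmax(round(ys), 1), shape[1]),
          pmin(pmax(round(xs), 1), shape[2]))] <- sgn
  k <- gaussian_kernel(gsd, 0L)
  z <- filter_separable(z, k, k)
  # an isolated impulse peaks at max(k)^2 after separable filtering;
  # rescale so each granule peaks at +/- amplitude
  z * (amplitude / max(k)^2)
}

# Anisotropic correlated noise at an arbitrary orientation: blur white
# noise along the axes of an oversized canvas (long axis along x), then
# rotate the whole field by theta (nearest-neighbour lookup) and crop the
# centre. Streak direction is theta, streak length ~ grain * aspect.
elongated_field <- function(shape, sd, grain, aspect, theta) {
  big <- ceiling(sqrt(2) * max(shape)) + 4L
  z <- matrix(stats::rnorm(big * big), big, big)
  kl <- gaussian_kernel(grain * aspect, 0L)
  ks <- gaussian_kernel(max(grain, 0.4), 0L)
  z <- filter_separable(z, kl, ks)      # long axis along x
  cy <- (big + 1) / 2; cx <- (big + 1) / 2
  yy <- matrix(seq_len(shape[1]) - (shape[1] + 1) / 2,
               shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]) - (shape[2] + 1) / 2,
               shape[1], shape[2], byrow = TRUE)
  sy <- round(cy + (-sin(theta)) * xx + cos(theta) * yy)
  sx <- round(cx + cos(theta) * xx + sin(theta) * yy)
  out <- matrix(z[cbind(pmin(pmax(as.vector(sy), 1), big),
                        pmin(pmax(as.vector(sx), 1), big))],
                shape[1], shape[2])
  out <- out - mean(out)
  out * (sd / stats::sd(as.vector(out)))
}

# Place n non-overlapping irregular discs; returns mask plus a list of
# (center, base radius). Radii are modulated by low-order angular
# harmonics so boundaries are blob-like rather than perfect circles.
place_objects <- function(spec) {
  rows <- spec$shape[1]; cols <- spec$shape[2]
  yy <- matrix(seq_len(rows), rows, cols)
  xx <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  mask <- matrix(FALSE, rows, cols)
  centers <- list()
  bump <- 0.12                      # harmonic amplitude of the boundary
  for (k in seq_len(spec$n_objects)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      r0 <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      a <- stats::runif(3, -bump, bump); ph <- stats::runif(3, 0, 2 * pi)
      rmax <- r0 * (1 + sum(abs(a)))
      margin <- rmax + 2
      cy <- stats::runif(1, margin, rows - margin)
      cx <- stats::runif(1, margin, cols - margin)
      ok <- all(vapply(centers, function(c0) {
        # objects must not overlap; halos of neighbours may touch
        sqrt((c0$cy - cy)^2 + (c0$cx - cx)^2) > c0$rmax + rmax + 1
      }, logical(1)))
      if (!ok) next
      th <- atan2(yy - cy, xx - cx)
      rth <- r0 * (1 + a[1] * cos(2 * th + ph[1]) +
                     a[2] * cos(3 * th + ph[2]) +
                     a[3] * cos(4 * th + ph[3]))
      obj <- ((yy - cy)^2 + (xx - cx)^2) <= rth^2
      mask <- mask | obj
      centers[[length(centers) + 1L]] <-
        list(cy = cy, cx = cx, r0 = r0, rmax = rmax)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", spec$n_objects,
           " non-overlapping objects; reduce n_objects or radii")
  }
  list(mask = mask, centers = centers)
}

# Euclidean distance from background pixels to the nearest object pixel.
distance_outside <- function(mask) {
  d <- EBImage::distmap(1 - mask, metric = "euclidean")
  d[mask] <- 0
  d
}

#' Generate a synthetic PCM image with exact ground truth
#'
#' Non-overlapping blob-like objects (harmonically perturbed discs) are
#' placed on a background composed of a base level, a smooth planar
#' illumination gradient and correlated granular noise. Object interiors
#' take `background_level * shade_off` plus their own texture; a bright
#' additive rim (`halo_amplitude`, decay `halo_width`) runs along the
#' outside of each boundary. The ground-truth mask is the exact object
#' support; the halo, being an artefact, is background.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `image` (numeric matrix), `mask` (0/1 integer
#'   matrix) and the echoed `spec`.
#' @export
generate_pcm_image <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  rows <- spec$shape[1]; cols <- spec$shape[2]
  pl <- place_objects(spec)
  mask <- pl$mask
  theta <- stats::runif(1, 0, 2 * pi)
  gx <- matrix(seq(0, 1, length.out = cols), rows, cols, byrow = TRUE)
  gy <- matrix(seq(0, 1, length.out = rows), rows, cols)
  grad <- spec$gradient_amplitude *
    (cos(theta) * (gx - 0.5) + sin(theta) * (gy - 0.5))
  bg_noise <- grain_field(spec$shape, spec$noise_sd, spec$noise_grain)
  fg_tex <- grain_field(spec$shape, spec$texture_sd, spec$texture_grain)
  img <- spec$background_level + bg_noise
  img[mask] <- spec$background_level * spec$shade_off + fg_tex[mask]
  if (spec$halo_amplitude != 0) {
    d <- distance_outside(mask)
    halo <- spec$halo_amplitude * exp(-0.5 * ((d - 1) / spec$halo_width)^2)
    halo[mask | d <= 0] <- 0
    img <- img + halo
  }
  img <- img + grad
  list(image = img, mask = matrix(as.integer(mask), rows, cols),
       spec = spec)
}

#' Specification for the co-culture (two-foreground-class) study
#'
#' [synthetic_spec()] with the geometry of a colony/feeder co-culture
#' field: a 256 x 256 crop holding one large monolithic colony of radius
#' 70-90 px surrounded by a feeder band half a radius wide. All texture
#' parameters are inherited from [synthetic_spec()].
#'
#' @param ... overrides passed on to [synthetic_spec()].
#' @return a `SyntheticSpec`.
#' @export
coculture_spec <- function(...) {
  args <- list(...)
  base <- list(shape = c(256L, 256L), n_objects = 1L,
               radius_range = c(70, 90))
  do.call(synthetic_spec, utils::modifyList(base, args))
}

#' Generate a synthetic co-culture image with three-class ground truth
#'
#' Emulates a colony/feeder co-culture: one or two large monolithic
#' regions (class A) whose interiors are quiet except for sparsely
#' scattered granules; a surrounding band of width about one class-A
#' radius tiled with fine, elongated class-B streaks; background
#' elsewhere. Class A and class B share the same base intensity (their
#' region means differ by well under 2% of the dynamic range), so
#' telling them apart requires texture, not brightness -- and because
#' class-A structure is sparse, requires a histogram window comparable
#' to the granule spacing.
#'
#' @param spec a [synthetic_spec()]; `radius_range` sizes the class-A
#'   regions, `granule_*` control the class-A texture and
#'   `texture_b_grain`/`texture_b_aspect`/`texture_sd` the class-B
#'   texture.
#' @return list with `image`, `labels` (integer matrix: 0 background,
#'   1 class A, 2 class B) and the echoed `spec`.
#' @export
generate_cocultured_image <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed + 7L)
  rows <- spec$shape[1]; cols <- spec$shape[2]
  pl <- place_objects(spec)
  a_mask <- pl$mask
  d <- distance_outside(a_mask)
  band <- 0.5 * mean(vapply(pl$centers, `[[`, numeric(1), "r0"))
  b_mask <- !a_mask & d > 0 & d <= band
  labels <- matrix(0L, rows, cols)
  labels[b_mask] <- 2L
  labels[a_mask] <- 1L
  level <- spec$background_level * spec$shade_off
  quiet_a <- grain_field(spec$shape, spec$noise_sd, spec$noise_grain)
  tex_a <- quiet_a + granule_field(spec$shape, spec$granule_density,
                                   spec$granule_sd,
                                   spec$granule_amplitude)
  theta_b <- stats::runif(1, 0, pi)
  tex_b <- elongated_field(spec$shape, spec$texture_sd,
                           spec$texture_b_grain, spec$texture_b_aspect,
                           theta_b)
  bg_noise <- grain_field(spec$shape, spec$noise_sd, spec$noise_grain)
  img <- spec$background_level + bg_noise
  img[a_mask] <- level + tex_a[a_mask] - mean(tex_a[a_mask])
  img[b_mask] <- level + tex_b[b_mask] - mean(tex_b[b_mask])
  theta <- stats::runif(1, 0, 2 * pi)
  gx <- matrix(seq(0, 1, length.out = cols), rows, cols, byrow = TRUE)
  gy <- matrix(seq(0, 1, length.out = rows), rows, cols)
  img <- img + spec$gradient_amplitude *
    (cos(theta) * (gx - 0.5) + sin(theta) * (gy - 0.5))
  list(image = img, labels = labels, spec = spec)
}

#' Generate a dataset of synthetic image/truth pairs
#'
#' Per-image seeds are spawned deterministically from `seed`, so the
#' dataset is reproducible and each image is independently regenerable.
#'
#' @param spec a [synthetic_spec()] used for every image (its own `seed`
#'   field is ignored).
#' @param n number of images.
#' @param seed master seed.
#' @param coculture if `TRUE`, use [generate_cocultured_image()].
#' @return list with `images`, `truths` (masks or 3-class labels) and
#'   `seeds` (the per-image seed ledger).
#' @export
generate_pcm_dataset <- function(spec, n, seed = 1L, coculture = FALSE) {
  seeds <- spawn_seeds(seed, n)
  gen <- if (coculture) generate_cocultured_image else generate_pcm_image
  out <- lapply(seeds, function(s) {
    sp <- spec; sp$seed <- s
    gen(sp)
  })
  list(images = lapply(out, `[[`, "image"),
       truths = lapply(out, function(o)
         if (coculture) o$labels else o$mask),
       seeds = seeds)
}
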