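# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's separable-convolution fast path:
# histograms are checked against direct Gaussian-weighted neighbourhood
# counting, BIF classification against an explicit per-pixel loop.

# Mirror indices into [1, n] (symmetric, edge repeated) -- written out
# independently of the package internals.
mirror_idx <- function(i, n) {
  i0 <- (i - 1) %% (2 * n)
  as.integer(ifelse(i0 < n, i0 + 1, 2 * n - i0))
}

# Brute-force soft local histograms: for every pixel, gather the label
# neighbourhood (mirrored at borders) and accumulate the normalised 2-D
# Gaussian weight of each class directly.
oracle_soft_histograms <- function(labels, n_classes, w) {
  sigma_w <- w / 2
  r <- ceiling(2 * sigma_w)
  x <- seq(-r, r)
  k2 <- outer(exp(-x^2 / (2 * sigma_w^2)), exp(-x^2 / (2 * sigma_w^2)))
  k2 <- k2 / sum(k2)
  kv <- as.vector(k2)
  nr <- nrow(labels); nc <- ncol(labels)
  offs <- expand.grid(dy = x, dx = x)
  # neighbour label matrix: one row per pixel, one column per offset
  pix <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  nbr <- matrix(0L, nrow(pix), nrow(offs))
  for (o in seq_len(nrow(offs))) {
    ri <- mirror_idx(pix$i + offs$dy[o], nr)
    cj <- mirror_idx(pix$j + offs$dx[o], nc)
    nbr[, o] <- labels[cbind(ri, cj)]
  }
  out <- array(0, c(nr, nc, n_classes))
  for (k in seq_len(n_classes))
    out[, , k] <- matrix((nbr == k - 1L) %*% kv, nr, nc)
  out
}

# Explicit-loop BIF classification from a response set: evaluates the
# seven measures per pixel and takes the first maximum.
oracle_classify <- function(responses, epsilon) {
  s <- responses
  nr <- nrow(s$s00); nc <- ncol(s$s00)
  out <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      lam <- s$s20[i, j] + s$s02[i, j]
      gam <- sqrt((s$s20[i, j] - s$s02[i, j])^2 + 4 * s$s11[i, j]^2)
      m <- c(epsilon * abs(s$s00[i, j]),
             2 * sqrt(s$s10[i, j]^2 + s$s01[i, j]^2),
             lam, -lam,
             (gam + lam) / sqrt(2), (gam - lam) / sqrt(2),
             gam)
      out[i, j] <- which.max(m) - 1L
    }
  }
  out
}

# Seven analytic 64 x 64 canon images, centred at pixel (33, 33), whose
# centre-pixel BIF class is known in closed form.
bif_canon_images <- function(n = 64L) {
  c0 <- (n + 2L) %/% 2L
  xx <- matrix(seq_len(n) - c0, n, n, byrow = TRUE)
  yy <- matrix(seq_len(n) - c0, n, n)
  list(flat        = xx * 0,
       slope       = 1.0 * xx,
       dark_blob   = xx^2 + yy^2,
       bright_blob = -(xx^2 + yy^2),
       dark_line   = xx^2,
       bright_line = -xx^2,
       saddle      = xx^2 - yy^2)
}

canon_centre <- function(n = 64L) (n + 2L) %/% 2L

# Fraction of the 2-px halo band (just outside each object) predicted as
# background.
halo_band_background_rate <- function(pred, mask) {
  d <- EBImage::distmap(1 - mask, metric = "euclidean")
  band <- d > 0 & d <= 2 & mask == 0
  mean(pred[band] == 0)
}

# Small, quick synthetic spec for unit tests (64 x 64, two small cells).
tiny_spec <- function(...) {
  synthetic_spec(shape = c(64L, 64L), n_objects = 2L,
                 radius_range = c(8, 12), ...)
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
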