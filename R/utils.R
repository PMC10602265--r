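# Internal helpers shared across modules.

# Coordinate convention (used everywhere): pixel (row i, col j) of an H x W
# field sits at the continuous position x = j (rightward), y = i (downward),
# both 1-based; gaze positions are continuous and may be sub-pixel.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

# Unit-peak isotropic Gaussian evaluated on the pixel grid, built separably.
unit_gaussian_field <- function(width, height, x0, y0, sigma_px) {
  gx <- exp(-((seq_len(width) - x0)^2) / (2 * sigma_px^2))
  gy <- exp(-((seq_len(height) - y0)^2) / (2 * sigma_px^2))
  outer(gy, gx)
}

# Bilinear interpolation of an H x W field at a continuous (x, y); out-of-range
# lookups clamp to the nearest edge.
bilinear_at <- function(field, x, y) {
  h <- nrow(field); w <- ncol(field)
  x <- min(max(x, 1), w); y <- min(max(y, 1), h)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1, w); y1 <- min(y0 + 1, h)
  fx <- x - x0; fy <- y - y0
  field[y0, x0] * (1 - fy) * (1 - fx) + field[y0, x1] * (1 - fy) * fx +
    field[y1, x0] * fy * (1 - fx) + field[y1, x1] * fy * fx
}

clip_to_frame <- function(pos, width, height) {
  c(min(max(pos[1], 1), width), min(max(pos[2], 1), height))
}

# Reproducible 32-bit sub-seed derivation for independent rng streams.
derive_seed <- function(base_seed, index) {
  as.integer((as.double(base_seed) * 48271 + as.double(index) * 16807) %% 2147483587) + 1L
}
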