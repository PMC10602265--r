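# Attentional fields: anisotropic centre bias, frame-wise combined feature
# maps, gaze-dependent visual sensitivity, and inhibition of return (IOR) in
# its space-bound and object-bound forms.

#' Centre-bias parameters
#'
#' Anisotropic Gaussian prior for the content-independent tendency to look at
#' the display centre. With each axis normalised to \[-1, 1\], the map is
#' `exp(-x^2 / (2 vx) - y^2 * nu / (2 vx))`, i.e. the x-variance `vx` is used
#' in both terms and the anisotropy `nu` scales the y exponent, making the
#' prior wider along y for `nu < 1`.
#'
#' @param variance_x Variance of the normalised x coordinate (default 0.22).
#' @param anisotropy Anisotropy ratio `nu` in (0, 1] (default 0.45).
#' @return An object of class `center_bias_params`.
#' @export
center_bias_params <- function(variance_x = 0.22, anisotropy = 0.45) {
  assert_scalar(variance_x, "variance_x", 1e-12)
  assert_scalar(anisotropy, "anisotropy", 1e-12, 1)
  structure(list(variance_x = variance_x, anisotropy = anisotropy),
            class = "center_bias_params")
}

#' Centre-bias map
#'
#' @param width,height Frame size in pixels.
#' @param params A [center_bias_params()].
#' @return H x W field in (0, 1\] with value 1 at the image centre. Each axis
#'   is normalised to \[-1, 1\] over its own half-extent.
#' @export
center_bias_map <- function(width, height, params = center_bias_params()) {
  xc <- (width + 1) / 2; yc <- (height + 1) / 2
  xt <- if (width > 1) (seq_len(width) - xc) / ((width - 1) / 2) else 0
  yt <- if (height > 1) (seq_len(height) - yc) / ((height - 1) / 2) else 0
  gx <- exp(-xt^2 / (2 * params$variance_x))
  gy <- exp(-yt^2 * params$anisotropy / (2 * params$variance_x))
  outer(gy, gx)
}

#' Combined per-frame feature map
#'
#' Normalises the scene's feature frame by its maximum and multiplies it with
#' the centre bias. `source = "none"` ignores the scene content entirely and
#' returns the centre bias alone (centre-bias-only models); `"lowlevel"` and
#' `"highlevel"` both read the bundle's feature field (the distinction is
#' which kind of precomputed saliency was loaded into it). An all-zero frame
#' stays all-zero (no division blow-up).
#'
#' @param bundle A `scene_bundle`.
#' @param frame Frame index (1-based).
#' @param source One of `"lowlevel"`, `"highlevel"`, `"none"`.
#' @param cb_params A [center_bias_params()].
#' @return H x W field in \[0, 1\].
#' @export
combined_feature_map <- function(bundle, frame,
                                 source = c("lowlevel", "highlevel", "none"),
                                 cb_params = center_bias_params()) {
  source <- match.arg(source)
  if (frame < 1 || frame > bundle$n_frames)
    stop("frame index out of range", call. = FALSE)
  cb <- center_bias_map(bundle$width_px, bundle$height_px, cb_params)
  if (source == "none") return(cb)
  f <- bundle$features[, , frame]
  m <- max(f)
  if (m > 0) f <- f / m
  f * cb
}

#' Sensitivity parameters
#'
#' @param sigma_s Gaussian spread of visual sensitivity in dva (> 0).
#' @param mode `"space"` (Gaussian only) or `"object"` (Gaussian plus uniform
#'   sensitivity across the currently foveated object mask).
#' @return An object of class `sensitivity_params`.
#' @export
sensitivity_params <- function(sigma_s, mode = c("space", "object")) {
  assert_scalar(sigma_s, "sigma_s", 1e-12)
  structure(list(sigma_s = sigma_s, mode = match.arg(mode)),
            class = "sensitivity_params")
}

#' Gaze-dependent visual sensitivity map
#'
#' Unit-peak isotropic Gaussian of spread `sigma_s` (given in dva, converted
#' to pixels) centred on the current gaze position, modelling the acuity
#' fall-off with eccentricity. In object mode the covert spread of attention
#' across the foveated object is modelled by setting every pixel of the
#' foveated mask to exactly 1; foveating the background sets no region to 1.
#'
#' @param gaze Numeric `c(x, y)` in pixels, inside the frame.
#' @param params A [sensitivity_params()].
#' @param px_per_dva Pixels per dva.
#' @param width,height Frame size in pixels.
#' @param foveated_mask Optional H x W logical mask of the currently foveated
#'   object (object mode; may be all-`FALSE` when foveating the background).
#' @return H x W field in (0, 1\].
#' @export
sensitivity_map <- function(gaze, params, px_per_dva, width, height,
                            foveated_mask = NULL) {
  sig <- params$sigma_s * px_per_dva
  S <- unit_gaussian_field(width, height, gaze[1], gaze[2], sig)
  if (params$mode == "object" && !is.null(foveated_mask) && any(foveated_mask))
    S[foveated_mask] <- 1
  S
}

#' Inhibition-of-return parameters
#'
#' @param mode `"space"` (Gaussian inhibition around previous saccade targets
#'   in allocentric coordinates) or `"object"` (per-object inhibition that
#'   follows the object).
#' @param r Slope of the linear decay of inhibition per frame (> 0); full
#'   recovery takes `1/r` frames.
#' @param sigma_i Spatial extent of the inhibition in dva (space mode).
#' @param xi Within-object inhibition in \[0, 1\] applied to the currently
#'   foveated object (object mode; always 0 for the background).
#' @return An object of class `ior_params`.
#' @export
ior_params <- function(mode = c("space", "object"), r, sigma_i = NULL, xi = NULL) {
  mode <- match.arg(mode)
  assert_scalar(r, "r", 1e-12)
  if (mode == "space") assert_scalar(sigma_i, "sigma_i", 1e-12)
  else assert_scalar(xi, "xi", 0, 1)
  structure(list(mode = mode, r = r, sigma_i = sigma_i, xi = xi),
            class = "ior_params")
}

#' Space-based inhibition map
#'
#' Sum over the foveation history of unit-peak Gaussians of spread `sigma_i`
#' centred on previous saccade-target locations (fixed screen coordinates,
#' never updated with scene motion), each weighted by a linear decay
#' `max(0, 1 - (t - t_h) * r)` and the total clipped to 1. An empty history
#' gives an all-zero field; targets older than `1/r` frames contribute nothing.
#'
#' @param history `data.frame` with columns `x`, `y` (px) and `t` (frames,
#'   decision times, non-decreasing).
#' @param t Current time in frames; must not precede the latest history entry.
#' @param params An [ior_params()] with `mode = "space"`.
#' @param px_per_dva Pixels per dva.
#' @param width,height Frame size in pixels.
#' @return H x W field in \[0, 1\].
#' @export
inhibition_map_space <- function(history, t, params, px_per_dva, width, height) {
  stopifnot(params$mode == "space")
  if (is.null(history) || nrow(history) == 0L)
    return(matrix(0, height, width))
  if (t < max(history$t))
    stop("t precedes the latest history entry", call. = FALSE)
  w <- pmax(0, 1 - (t - history$t) * params$r)
  keep <- w > 0
  if (!any(keep)) return(matrix(0, height, width))
  sig <- params$sigma_i * px_per_dva
  xh <- history$x[keep]; yh <- history$y[keep]; w <- w[keep]
  # separable Gaussians: I = Gy %*% t(Gx * w), summed over history entries
  Gy <- exp(-outer(seq_len(height), yh, function(y, y0) (y - y0)^2) / (2 * sig^2))
  Gx <- exp(-outer(seq_len(width), xh, function(x, x0) (x - x0)^2) / (2 * sig^2))
  pmin(Gy %*% (t(Gx) * w), 1)
}

#' Object-based inhibition
#'
#' While an object is foveated its selection is inhibited by the within-object
#' factor `xi`; after the gaze leaves it the inhibition restarts at 1 and
#' decays linearly to 0 with slope `r` per frame. The background (id 0) is
#' never inhibited, and never-foveated objects carry no inhibition.
#'
#' @param history List with elements `foveated` (currently foveated object id,
#'   or `NA`) and `last_left` (named numeric: per object id, the time in
#'   frames when the gaze last left its mask).
#' @param t Current time in frames.
#' @param object_id Non-negative integer object id.
#' @param params An [ior_params()] with `mode = "object"`.
#' @return Scalar inhibition in \[0, 1\].
#' @export
inhibition_object <- function(history, t, object_id, params) {
  stopifnot(params$mode == "object")
  if (length(object_id) != 1L || is.na(object_id) || object_id < 0)
    stop("unknown object id", call. = FALSE)
  if (object_id == 0) return(0)
  if (!is.na(history$foveated) && history$foveated == object_id)
    return(params$xi)
  key <- as.character(object_id)
  if (!key %in% names(history$last_left)) return(0)
  max(0, 1 - params$r * (t - history$last_left[[key]]))
}
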