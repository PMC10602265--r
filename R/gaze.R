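# Gaze update during foveation (smooth pursuit + fixational jitter) and
# saccade landing.

#' Smooth-pursuit gaze drift during foveation
#'
#' Object mode shifts the gaze by the displacement of the foveated object's
#' centre of mass between `frame` and `frame + 1` (background, no object, or
#' an object absent in either frame gives no shift). Flow mode shifts the
#' gaze by the optical-flow vector bilinearly interpolated at the gaze
#' position (out-of-range lookups clamp to the nearest edge). The result is
#' clipped to the frame.
#'
#' @param gaze Numeric `c(x, y)` in px.
#' @param bundle A `scene_bundle`.
#' @param frame Current frame index; `frame + 1` must exist for a shift.
#' @param mode `"object"` or `"flow"`.
#' @param object_id Foveated object id (object mode; 0/`NA` = background).
#' @return Updated `c(x, y)`.
#' @export
foveation_drift <- function(gaze, bundle, frame, mode = c("object", "flow"),
                            object_id = NULL) {
  mode <- match.arg(mode)
  if (frame + 1 > bundle$n_frames) return(gaze)
  if (mode == "object") {
    if (is.null(object_id) || is.na(object_id) || object_id == 0) return(gaze)
    reg <- bundle$object_registry
    a <- reg[reg$object_id == object_id & reg$frame == frame, ]
    b <- reg[reg$object_id == object_id & reg$frame == frame + 1, ]
    if (nrow(a) != 1L || nrow(b) != 1L) return(gaze)
    shift <- c(b$cx - a$cx, b$cy - a$cy)
  } else {
    shift <- c(bilinear_at(bundle$flow[, , frame, 1], gaze[1], gaze[2]),
               bilinear_at(bundle$flow[, , frame, 2], gaze[1], gaze[2]))
  }
  clip_to_frame(gaze + shift, bundle$width_px, bundle$height_px)
}

#' Fixational jitter
#'
#' Brownian fixational eye movements: adds independent normal displacements
#' with sd `sigma_d` (dva, converted to px) to each coordinate, once per
#' foveation frame -- during fixation and smooth pursuit alike. The result is
#' clipped to the frame.
#'
#' @param gaze Numeric `c(x, y)` in px.
#' @param sigma_d Random-walk sd in dva per frame (>= 0; default 0.125).
#' @param px_per_dva Pixels per dva.
#' @param width,height Frame size in px.
#' @return Updated `c(x, y)`.
#' @export
fixational_jitter <- function(gaze, sigma_d = 0.125, px_per_dva, width, height) {
  assert_scalar(sigma_d, "sigma_d", 0)
  if (sigma_d == 0) return(gaze)
  clip_to_frame(gaze + stats::rnorm(2, 0, sigma_d * px_per_dva), width, height)
}

#' Saccade landing position
#'
#' Space mode lands exactly on the winning pixel. Object mode samples the
#' landing over the winning object's mask with per-pixel probability
#' proportional to features times sensitivity at decision time (inhibition is
#' uniform within an object and drops out); if all weights are zero the
#' landing is uniform over the mask.
#'
#' @param mode `"space"` or `"object"`.
#' @param winner_pixel Space mode: `c(x, y)` of the winning pixel.
#' @param mask Object mode: H x W logical mask of the winning object
#'   (non-empty).
#' @param weights Object mode: H x W field of `F * S` at decision time.
#' @return Landing position `c(x, y)` in px.
#' @export
saccade_landing <- function(mode = c("space", "object"), winner_pixel = NULL,
                            mask = NULL, weights = NULL) {
  mode <- match.arg(mode)
  if (mode == "space") {
    stopifnot(length(winner_pixel) == 2L)
    return(as.numeric(winner_pixel))
  }
  idx <- which(mask)
  if (!length(idx)) stop("empty target mask", call. = FALSE)
  w <- weights[idx]
  pick <- if (length(idx) == 1L) idx else if (sum(w) > 0)
    idx[sample.int(length(idx), 1L, prob = w)] else
    idx[sample.int(length(idx), 1L)]
  h <- nrow(mask)
  c(((pick - 1L) %/% h) + 1L, ((pick - 1L) %% h) + 1L)
}
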