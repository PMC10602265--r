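# Scene data model: per-frame feature, object-label and optical-flow fields,
# synthetic scene generation, HDF5 archives, validation, and the
# time-reversed / doubly-mirrored control transform.

#' Specification for a synthetic dynamic scene
#'
#' Describes a scene of moving labelled objects with feature blobs co-located
#' with the objects and optical flow consistent with the object motion. The
#' generated scenes stand in for natural-video inputs (frame-wise saliency
#' maps, temporally consistent segmentation masks, and optical flow) so the
#' whole simulation and fitting pipeline runs without external data.
#'
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames (default 300, i.e. 10 s at 30 fps).
#' @param fps Frames per second (default 30).
#' @param px_per_dva Pixels per degree of visual angle. The default (2) makes
#'   the default frame span 40 x 30 dva, a typical free-viewing display.
#' @param objects `data.frame` with one row per object and columns
#'   `shape` ("ellipse" or "rectangle"), `width_px`, `height_px` (full extents),
#'   `x0`, `y0` (initial centre), `vx`, `vy` (constant velocity in px/frame),
#'   `feature_amplitude` in (0, 1], and `feature_width_px` (Gaussian blob sd).
#'   Object ids are assigned 1..n in row order; on overlap the higher id wins.
#' @param background_level Background feature level in \[0, 1).
#' @param noise_sd Additive Gaussian feature noise sd (>= 0); features are
#'   clipped to \[0, 1\] after adding noise.
#' @param seed Integer seed making generation deterministic.
#' @return An object of class `synth_spec`.
#' @seealso [synth_scene()]
#' @export
synth_spec <- function(width = 80L, height = 60L, n_frames = 300L, fps = 30,
                       px_per_dva = 2, objects, background_level = 0.1,
                       noise_sd = 0.02, seed = 1L) {
  assert_scalar(width, "width", 1); assert_scalar(height, "height", 1)
  assert_scalar(n_frames, "n_frames", 1); assert_scalar(fps, "fps", 1e-6)
  assert_scalar(px_per_dva, "px_per_dva", 1e-6)
  assert_scalar(background_level, "background_level", 0, 1 - 1e-12)
  assert_scalar(noise_sd, "noise_sd", 0)
  stopifnot(is.data.frame(objects), nrow(objects) >= 1)
  needed <- c("shape", "width_px", "height_px", "x0", "y0", "vx", "vy",
              "feature_amplitude", "feature_width_px")
  missing <- setdiff(needed, names(objects))
  if (length(missing))
    stop("`objects` lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (any(objects$feature_amplitude <= 0 | objects$feature_amplitude > 1))
    stop("object feature amplitudes must lie in (0, 1]", call. = FALSE)
  if (any(objects$width_px <= 0 | objects$height_px <= 0 | objects$feature_width_px <= 0))
    stop("object sizes must be positive", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames), fps = fps,
                 px_per_dva = px_per_dva, objects = objects,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

object_mask <- function(shape, cx, cy, w, h, width, height) {
  xs <- seq_len(width); ys <- seq_len(height)
  if (shape == "rectangle") {
    outer(abs(ys - cy) <= h / 2, abs(xs - cx) <= w / 2, `&`)
  } else {
    outer(((ys - cy) / (h / 2))^2, ((xs - cx) / (w / 2))^2, `+`) <= 1
  }
}

build_registry <- function(labels) {
  dims <- dim(labels)
  rows <- vector("list", dims[3])
  for (t in seq_len(dims[3])) {
    lab <- labels[, , t]
    ids <- sort(unique(lab[lab > 0L]))
    if (!length(ids)) next
    rows[[t]] <- do.call(rbind, lapply(ids, function(i) {
      idx <- which(lab == i)
      ri <- ((idx - 1L) %% dims[1]) + 1L
      ci <- ((idx - 1L) %/% dims[1]) + 1L
      data.frame(object_id = i, frame = t, n_px = length(idx),
                 cx = mean(ci), cy = mean(ri))
    }))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(object_id = integer(), frame = integer(), n_px = integer(),
                      cx = numeric(), cy = numeric())
  rownames(out) <- NULL
  out
}

#' Generate a synthetic dynamic scene
#'
#' Builds a [scene bundle][validate_scene]: per-frame feature field in
#' \[0, 1\] (background level + per-object Gaussian blobs centred on the
#' object centroids + clipped noise), an integer label field (0 = background),
#' flow equal to each object's velocity inside its mask and zero elsewhere,
#' and a per-frame object registry (mask sizes and centroids).
#'
#' @param spec A [synth_spec()].
#' @return An object of class `scene_bundle` with elements `scene_id`,
#'   `width_px`, `height_px`, `n_frames`, `fps`, `px_per_dva`, `features`
#'   (H x W x T array), `objects` (H x W x T integer array), `flow`
#'   (H x W x T x 2 array, components dx then dy, px/frame), and
#'   `object_registry`.
#' @export
synth_scene <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  W <- spec$width; H <- spec$height; T <- spec$n_frames
  obj <- spec$objects
  n_obj <- nrow(obj)
  labels <- array(0L, c(H, W, T))
  features <- array(0, c(H, W, T))
  flow <- array(0, c(H, W, T, 2))
  seen <- logical(n_obj)
  for (t in seq_len(T)) {
    lab <- matrix(0L, H, W)
    feat <- matrix(spec$background_level, H, W)
    fx <- matrix(0, H, W); fy <- matrix(0, H, W)
    for (o in seq_len(n_obj)) {
      cx <- obj$x0[o] + obj$vx[o] * (t - 1)
      cy <- obj$y0[o] + obj$vy[o] * (t - 1)
      m <- object_mask(obj$shape[o], cx, cy, obj$width_px[o], obj$height_px[o], W, H)
      if (any(m)) {
        seen[o] <- TRUE
        lab[m] <- o
        fx[m] <- obj$vx[o]; fy[m] <- obj$vy[o]
      }
      # feature blob rides on the object centre whether or not it is on-frame
      feat <- feat + obj$feature_amplitude[o] *
        unit_gaussian_field(W, H, cx, cy, obj$feature_width_px[o])
    }
    if (spec$noise_sd > 0)
      feat <- feat + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    features[, , t] <- pmin(pmax(feat, 0), 1)
    labels[, , t] <- lab
    # flow belongs to the pixel's owner after overlap resolution
    fx[lab == 0L] <- 0; fy[lab == 0L] <- 0
    flow[, , t, 1] <- fx; flow[, , t, 2] <- fy
    if (!any(lab == 0L))
      stop("no background pixel left in frame ", t, call. = FALSE)
  }
  if (any(!seen))
    stop("object(s) ", paste(which(!seen), collapse = ", "),
         " fully outside the frame for all frames", call. = FALSE)
  structure(list(scene_id = paste0("synth-", spec$seed),
                 width_px = W, height_px = H, n_frames = T, fps = spec$fps,
                 px_per_dva = spec$px_per_dva, features = features,
                 objects = labels, flow = flow,
                 object_registry = build_registry(labels)),
            class = "scene_bundle")
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf("<scene_bundle '%s'> %d x %d px, %d frames @ %g fps, %g px/dva, %d object id(s)\n",
              x$scene_id, x$width_px, x$height_px, x$n_frames, x$fps,
              x$px_per_dva, length(unique(x$object_registry$object_id))))
  invisible(x)
}

#' Save a scene bundle to an HDF5 archive
#'
#' One file per scene with datasets `features` (float64), `objects` (integer)
#' and `flow` (float64), plus root attributes `scene_id`, `fps` and
#' `px_per_dva`. The round trip through [load_scene()] reproduces all fields
#' bit-exactly; the object registry is recomputed from the label field on load.
#'
#' @param bundle A `scene_bundle`.
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
save_scene <- function(bundle, path) {
  stopifnot(inherits(bundle, "scene_bundle"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(bundle$features, path, "features")
  rhdf5::h5write(bundle$objects, path, "objects")
  rhdf5::h5write(bundle$flow, path, "flow")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(bundle$scene_id, fid, "scene_id")
  rhdf5::h5writeAttribute(bundle$fps, fid, "fps")
  rhdf5::h5writeAttribute(bundle$px_per_dva, fid, "px_per_dva")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Load a scene bundle from an HDF5 archive
#'
#' @param path Path written by [save_scene()].
#' @return A `scene_bundle`. Structured errors name the offending field
#'   (missing dataset, shape mismatch, out-of-range features, non-finite flow).
#' @export
load_scene <- function(path) {
  if (!file.exists(path)) stop("no such scene archive: ", path, call. = FALSE)
  present <- rhdf5::h5ls(path)$name
  for (ds in c("features", "objects", "flow"))
    if (!ds %in% present) stop(ds, " missing from scene archive", call. = FALSE)
  features <- rhdf5::h5read(path, "features")
  labels <- rhdf5::h5read(path, "objects")
  flow <- rhdf5::h5read(path, "flow")
  att <- rhdf5::h5readAttributes(path, "/")
  storage.mode(labels) <- "integer"
  if (length(dim(features)) != 3L || length(dim(flow)) != 4L ||
      !identical(dim(features), dim(labels)) ||
      !identical(dim(flow), c(dim(features), 2L)))
    stop("shape mismatch between features/objects/flow", call. = FALSE)
  if (any(features < 0) || any(features > 1))
    stop("features out of range [0, 1]", call. = FALSE)
  if (any(!is.finite(flow)))
    stop("flow contains non-finite values", call. = FALSE)
  d <- dim(features)
  structure(list(scene_id = as.character(att$scene_id %||% "scene"),
                 width_px = d[2], height_px = d[1], n_frames = d[3],
                 fps = as.numeric(att$fps %||% 30),
                 px_per_dva = as.numeric(att$px_per_dva %||% 1),
                 features = features, objects = labels, flow = flow,
                 object_registry = build_registry(labels)),
            class = "scene_bundle")
}

#' Validate a scene bundle
#'
#' Reports (never raises) violations of the scene invariants: shared geometry
#' across fields, features in \[0, 1\], non-negative integer labels, finite
#' flow, at least one background pixel per frame, registry centroids matching
#' the label field, and the exclusion rule for scenes with more than 100
#' distinct object ids.
#'
#' @param bundle A `scene_bundle`.
#' @return Character vector of violation messages; empty iff the bundle is valid.
#' @export
validate_scene <- function(bundle) {
  out <- character()
  d <- c(bundle$height_px, bundle$width_px, bundle$n_frames)
  if (!identical(dim(bundle$features), as.integer(d)) &&
      !identical(dim(bundle$features), d))
    out <- c(out, "features: geometry mismatch with metadata")
  if (!identical(dim(bundle$features), dim(bundle$objects)))
    out <- c(out, "objects: shape mismatch with features")
  if (!identical(dim(bundle$flow)[1:3], dim(bundle$features)) ||
      dim(bundle$flow)[4] != 2L)
    out <- c(out, "flow: shape mismatch with features")
  if (any(bundle$features < 0 | bundle$features > 1))
    out <- c(out, "features: values outside [0, 1]")
  if (any(bundle$objects < 0) || !is.integer(bundle$objects))
    out <- c(out, "objects: labels must be non-negative integers")
  if (any(!is.finite(bundle$flow)))
    out <- c(out, "flow: non-finite values")
  for (t in seq_len(bundle$n_frames))
    if (!any(bundle$objects[, , t] == 0L)) {
      out <- c(out, sprintf("objects: no background pixel in frame %d", t))
      break
    }
  n_ids <- length(unique(bundle$object_registry$object_id))
  if (n_ids > 100)
    out <- c(out, sprintf("objects: exceeds 100 object IDs (%d assigned)", n_ids))
  ref <- build_registry(bundle$objects)
  reg <- bundle$object_registry
  if (!isTRUE(all.equal(ref[order(ref$object_id, ref$frame), c("cx", "cy")],
                        reg[order(reg$object_id, reg$frame), c("cx", "cy")],
                        tolerance = 1e-9, check.attributes = FALSE)) ||
      nrow(ref) != nrow(reg))
    out <- c(out, "object_registry: centroids inconsistent with label field")
  out
}

#' Control transform: time reversal plus double mirroring
#'
#' Reverses the frame order and mirrors every field on both image axes, so
#' scanpaths (kept unchanged) no longer correlate with the scene's object
#' content. Flow vectors are negated for the time reversal and each component
#' is sign-flipped again for its mirrored axis, so the stored components are
#' unchanged while the fields are re-indexed; an object moving right still
#' moves right. The transform is an involution.
#'
#' @param bundle A `scene_bundle`.
#' @return The transformed `scene_bundle` (object ids preserved, registry
#'   recomputed).
#' @export
transform_scene <- function(bundle) {
  stopifnot(inherits(bundle, "scene_bundle"))
  ri <- rev(seq_len(bundle$height_px))
  ci <- rev(seq_len(bundle$width_px))
  ti <- rev(seq_len(bundle$n_frames))
  out <- bundle
  out$features <- bundle$features[ri, ci, ti, drop = FALSE]
  out$objects <- bundle$objects[ri, ci, ti, drop = FALSE]
  out$flow <- bundle$flow[ri, ci, ti, , drop = FALSE]   # -1 (time) * -1 (mirror)
  out$object_registry <- build_registry(out$objects)
  out
}
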