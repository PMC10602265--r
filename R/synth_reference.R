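# Synthetic "human-like" reference scanpaths: event tables whose foveation
# durations are log-normal and saccade amplitudes Gamma distributed (the
# forms fitted to free-viewing eye-tracking data), placed on a scene with a
# landing policy biased toward object masks. Provides the ground truth that
# makes the evaluation and fitting pipeline testable without eye-tracking
# data, plus a model-as-reference mode for parameter recovery.

#' Specification of a synthetic reference observer population
#'
#' @param n_subjects Number of observers (default 12).
#' @param fd_meanlog,fd_sdlog Log-normal parameters of foveation durations in
#'   ms (defaults 5.735 and 0.838; expected value
#'   `exp(meanlog + sdlog^2 / 2)` = 439.6 ms).
#' @param sa_shape,sa_scale Gamma shape and scale of saccade amplitudes in
#'   dva (defaults 1.43 and 6.50).
#' @param p_object Probability that a saccade is aimed at an object mask
#'   rather than in a random direction (default 0.6: free-viewing observers
#'   spend the majority of their time on foreground objects).
#' @param seed Integer seed.
#' @return An object of class `reference_spec`.
#' @export
reference_spec <- function(n_subjects = 12L, fd_meanlog = 5.735,
                           fd_sdlog = 0.838, sa_shape = 1.43, sa_scale = 6.50,
                           p_object = 0.6, seed = 1L) {
  assert_scalar(n_subjects, "n_subjects", 1)
  assert_scalar(fd_sdlog, "fd_sdlog", 1e-12)
  assert_scalar(sa_shape, "sa_shape", 1e-12)
  assert_scalar(sa_scale, "sa_scale", 1e-12)
  assert_scalar(p_object, "p_object", 0, 1)
  structure(list(n_subjects = as.integer(n_subjects), fd_meanlog = fd_meanlog,
                 fd_sdlog = fd_sdlog, sa_shape = sa_shape, sa_scale = sa_scale,
                 p_object = p_object, seed = as.integer(seed)),
            class = "reference_spec")
}

#' Generate a synthetic reference event table on a scene
#'
#' Each subject's scanpath starts at the frame centre and alternates
#' foveations (log-normal durations) and saccades (Gamma amplitudes, duration
#' from the amplitude-duration law) until the video duration is tiled; the
#' last foveation absorbs the remaining time. With probability `p_object` a
#' saccade lands on a uniformly chosen pixel of a random object present at
#' its onset (the realised amplitude then is the distance to it); otherwise
#' the drawn amplitude is applied in a uniformly random direction (redrawn up
#' to 20 times to stay on-frame, then clamped). Foveations on an object
#' follow its centroid (smooth pursuit); object ids are assigned with the
#' 1-dva rule of [object_at_gaze()]. Deterministic given `spec$seed`.
#'
#' @param spec A [reference_spec()].
#' @param bundle A `scene_bundle`.
#' @return Event table (one `run_id` per subject) in the common schema.
#' @export
synth_reference <- function(spec, bundle) {
  stopifnot(inherits(spec, "reference_spec"), inherits(bundle, "scene_bundle"))
  fd <- 1000 / bundle$fps; total <- bundle$n_frames * fd
  W <- bundle$width_px; H <- bundle$height_px; ppd <- bundle$px_per_dva
  if (stats::qlnorm(0.01, spec$fd_meanlog, spec$fd_sdlog) > total)
    stop("foveation-duration distribution cannot fit a single event in the video",
         call. = FALSE)
  out <- list(); k <- 0L
  for (subj in seq_len(spec$n_subjects)) {
    set.seed(derive_seed(spec$seed, subj))
    t <- 0; pos <- c((W + 1) / 2, (H + 1) / 2)
    repeat {
      d <- stats::rlnorm(1, spec$fd_meanlog, spec$fd_sdlog)
      final <- t + d >= total
      if (final) d <- total - t
      frame0 <- min(floor(t / fd) + 1, bundle$n_frames)
      obj <- object_at_gaze(bundle, frame0, pos[1], pos[2])
      frame1 <- min(floor((t + d) / fd) + 1, bundle$n_frames)
      end_pos <- pos
      if (obj > 0L) {        # pursue the foveated object's centroid
        reg <- bundle$object_registry
        a <- reg[reg$object_id == obj & reg$frame == frame0, ]
        b <- reg[reg$object_id == obj & reg$frame == frame1, ]
        if (nrow(a) == 1L && nrow(b) == 1L)
          end_pos <- clip_to_frame(pos + c(b$cx - a$cx, b$cy - a$cy), W, H)
      }
      k <- k + 1L
      out[[k]] <- data.frame(scene_id = bundle$scene_id, run_id = subj,
                             event_type = "fov", t_start_ms = t, t_end_ms = t + d,
                             x_start_px = pos[1], y_start_px = pos[2],
                             x_end_px = end_pos[1], y_end_px = end_pos[2],
                             object_id = obj, amplitude_dva = NA_real_,
                             truncated = FALSE, stringsAsFactors = FALSE)
      t <- t + d; pos <- end_pos
      if (final || t >= total) break
      a_dva <- stats::rgamma(1, shape = spec$sa_shape, scale = spec$sa_scale)
      frame_t <- min(floor(t / fd) + 1, bundle$n_frames)
      lab <- bundle$objects[, , frame_t]
      ids <- sort(unique(lab[lab > 0L]))
      if (length(ids) && stats::runif(1) < spec$p_object) {
        target <- ids[sample.int(length(ids), 1)]
        idx <- which(lab == target)
        pick <- idx[sample.int(length(idx), 1)]
        land <- c(((pick - 1L) %/% H) + 1L, ((pick - 1L) %% H) + 1L)
      } else {
        a_px <- a_dva * ppd
        land <- NULL
        for (try in seq_len(20)) {
          angle <- stats::runif(1, 0, 2 * pi)
          cand <- pos + a_px * c(cos(angle), sin(angle))
          if (cand[1] >= 1 && cand[1] <= W && cand[2] >= 1 && cand[2] <= H) {
            land <- cand; break
          }
        }
        if (is.null(land)) land <- clip_to_frame(cand, W, H)
      }
      amp <- sqrt(sum((land - pos)^2)) / ppd
      tau <- saccade_duration(amp)
      trunc <- t + tau > total
      k <- k + 1L
      out[[k]] <- data.frame(scene_id = bundle$scene_id, run_id = subj,
                             event_type = "sac", t_start_ms = t,
                             t_end_ms = min(t + tau, total),
                             x_start_px = pos[1], y_start_px = pos[2],
                             x_end_px = land[1], y_end_px = land[2],
                             object_id = NA_integer_, amplitude_dva = amp,
                             truncated = trunc, stringsAsFactors = FALSE)
      t <- t + tau; pos <- land
      if (t >= total) break
    }
  }
  events <- do.call(rbind, out)
  events$duration_ms <- events$t_end_ms - events$t_start_ms
  attr(events, "provenance") <- "reference"
  events
}

#' Use a model's own output as reference data
#'
#' Runs the simulator and re-tags the output as reference, recording the
#' generating parameters alongside -- the ground truth for parameter-recovery
#' experiments.
#'
#' @param bundles A `scene_bundle` or list of them.
#' @param spec A [model_spec()].
#' @param n_runs Scanpaths per scene (default 12).
#' @param seed Integer base seed.
#' @return Event table with attributes `provenance = "reference"` and
#'   `ground_truth` (the generating `model_spec`).
#' @export
model_as_reference <- function(bundles, spec, n_runs = 12L, seed = 1L) {
  events <- run_batch(bundles, spec, n_runs = n_runs, base_seed = seed)
  attr(events, "provenance") <- "reference"
  attr(events, "ground_truth") <- spec
  events
}
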