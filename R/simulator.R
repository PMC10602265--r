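# Model variants and the scanpath simulator: one full scanpath per
# (scene, model, seed), with event bookkeeping at sub-frame resolution.

variant_table <- list(
  S.ll = list(selection = "space",  source = "lowlevel",  ior = "space",
              sigma_s = 12.51, theta = 0.384, s = 0.011, inv_r = 253.3, sigma_i = 7.79),
  S.hl = list(selection = "space",  source = "highlevel", ior = "space",
              sigma_s = 10.71, theta = 1.715, s = 0.092, inv_r = 296.0, sigma_i = 4.51),
  M.ll = list(selection = "object", source = "lowlevel",  ior = "space",
              sigma_s = 9.09,  theta = 1.068, s = 0.247, inv_r = 170.6, sigma_i = 6.06),
  O.ll = list(selection = "object", source = "lowlevel",  ior = "object",
              sigma_s = 13.75, theta = 2.128, s = 0.230, inv_r = 272.0, xi = 0.72),
  O.cb = list(selection = "object", source = "none",      ior = "object",
              sigma_s = 5.81,  theta = 2.973, s = 0.236, inv_r = 159.4, xi = 0.95)
)

#' Model specification for one scanpath-model variant
#'
#' A variant decomposes into a selection mode (space: every pixel is a race
#' target; object: every segmentation mask is), a feature source (low- or
#' high-level saliency, or centre bias only), and an IOR mode (space- or
#' object-bound):
#' `S.ll`/`S.hl` = space selection + space IOR with low-/high-level features,
#' `O.ll` = object selection + object IOR, `O.cb` = the same with no scene
#' features (centre bias only), and `M.ll` = object selection with space IOR.
#' Default free parameters are the published best-fitness values per variant;
#' any of them can be overridden.
#'
#' @param variant One of `"S.ll"`, `"S.hl"`, `"O.ll"`, `"O.cb"`, `"M.ll"`.
#' @param sigma_s Sensitivity spread (dva).
#' @param theta DDM decision threshold.
#' @param s DDM noise level.
#' @param r IOR decay slope per frame (`1/r` frames to full recovery).
#' @param sigma_i Space-IOR extent (dva; space-IOR variants).
#' @param xi Within-object inhibition in \[0, 1\] (object-IOR variants).
#' @param sigma_d Fixational random-walk sd (dva/frame; fixed, default 0.125).
#' @param cb_params A [center_bias_params()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(variant = c("O.ll", "S.ll", "S.hl", "O.cb", "M.ll"),
                       sigma_s = NULL, theta = NULL, s = NULL, r = NULL,
                       sigma_i = NULL, xi = NULL, sigma_d = 0.125,
                       cb_params = center_bias_params()) {
  variant <- match.arg(variant)
  def <- variant_table[[variant]]
  spec <- list(variant = variant, selection = def$selection,
               source = def$source, ior = def$ior,
               sigma_s = sigma_s %||% def$sigma_s,
               theta = theta %||% def$theta,
               s = s %||% def$s,
               r = r %||% (1 / def$inv_r),
               sigma_i = sigma_i %||% def$sigma_i,
               xi = xi %||% def$xi,
               sigma_d = sigma_d, cb_params = cb_params)
  assert_scalar(spec$sigma_s, "sigma_s", 1e-12)
  assert_scalar(spec$theta, "theta", 1e-12)
  assert_scalar(spec$s, "s", 0)
  assert_scalar(spec$r, "r", 1e-12)
  if (spec$ior == "space") assert_scalar(spec$sigma_i, "sigma_i", 1e-12)
  else assert_scalar(spec$xi, "xi", 0, 1)
  assert_scalar(spec$sigma_d, "sigma_d", 0)
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s> selection=%s features=%s ior=%s\n",
              x$variant, x$selection, x$source, x$ior))
  cat(sprintf("  sigma_s=%g theta=%g s=%g r=%g %s sigma_d=%g\n",
              x$sigma_s, x$theta, x$s, x$r,
              if (x$ior == "space") sprintf("sigma_i=%g", x$sigma_i)
              else sprintf("xi=%g", x$xi), x$sigma_d))
  invisible(x)
}

# Per-scene quantities that do not depend on the gaze or on free parameters
# other than the (fixed) centre bias: combined feature maps and per-frame
# object-mask indices. Sharing this across runs/individuals keeps fitting fast.
scene_precompute <- function(bundle, spec) {
  T <- bundle$n_frames; H <- bundle$height_px; W <- bundle$width_px
  feats <- vector("list", T)
  masks <- vector("list", T)
  for (t in seq_len(T)) {
    feats[[t]] <- combined_feature_map(bundle, t, spec$source, spec$cb_params)
    lab <- bundle$objects[, , t]
    ids <- sort(unique(as.integer(lab)))
    idx <- lapply(ids, function(i) which(lab == i))
    names(idx) <- as.character(ids)
    masks[[t]] <- list(ids = ids, idx = idx, labels = lab)
  }
  # per-frame centroid lookup (NA where absent) for fast pursuit updates
  reg <- bundle$object_registry
  max_id <- max(c(0L, reg$object_id))
  cent <- array(NA_real_, c(max_id, T, 2))
  if (nrow(reg)) {
    cent[cbind(reg$object_id, reg$frame, 1L)] <- reg$cx
    cent[cbind(reg$object_id, reg$frame, 2L)] <- reg$cy
  }
  list(features = feats, masks = masks, cent = cent)
}

#' Simulate one scanpath
#'
#' Runs the full per-frame loop: combined feature map, gaze-centred
#' sensitivity (object variants add the foveated mask), inhibition per IOR
#' mode, drift rates per selection mode (the mixed model feeds the spatial
#' inhibition field into the object-rate sum), one race update per frame with
#' the frame's foveation fraction, and linear interpolation of the exact
#' threshold-crossing time. On a crossing the foveation event is closed, the
#' landing and amplitude-dependent saccade duration are computed, all
#' accumulators are reset, and the scanpath history is updated (space IOR:
#' landing position and decision time in screen coordinates; object IOR: the
#' left object's last-foveated time). Between decisions the gaze follows the
#' foveated object's centroid (object variants) or the optical flow (space
#' variants), plus Brownian fixational jitter. Saccades shorter than a frame
#' are handled by processing multiple foveation segments per frame (maps are
#' evaluated once per frame; the sensitivity is re-centred after an
#' intra-frame landing). A saccade spanning the video end is truncated at the
#' last frame and flagged.
#'
#' The simulation starts at frame 0 foveating the frame centre and is fully
#' deterministic given `seed`.
#'
#' @param bundle A `scene_bundle`.
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @param run_id Identifier stored in the output tables.
#' @param precomp Optional result of the internal per-scene precomputation
#'   (shared across runs for speed); computed when `NULL`.
#' @param keep_trace Keep the per-frame gaze trace (default `TRUE`).
#' @return An object of class `scanpath`: list with `events` (the event
#'   table: columns `scene_id`, `run_id`, `event_type` ("fov"/"sac"),
#'   `t_start_ms`, `t_end_ms`, `x_start_px`, `y_start_px`, `x_end_px`,
#'   `y_end_px`, `object_id`, `amplitude_dva`, `duration_ms`, `truncated`)
#'   and `trace` (per-frame `frame`, `t_ms`, `x_px`, `y_px`, `state`,
#'   `object_id`).
#' @export
simulate_scanpath <- function(bundle, spec, seed = 1L, run_id = 1L,
                              precomp = NULL, keep_trace = TRUE) {
  stopifnot(inherits(bundle, "scene_bundle"), inherits(spec, "model_spec"))
  set.seed(seed)
  W <- bundle$width_px; H <- bundle$height_px; T <- bundle$n_frames
  fd <- 1000 / bundle$fps; total <- T * fd
  ppd <- bundle$px_per_dva
  pc <- precomp %||% scene_precompute(bundle, spec)
  obj_sel <- spec$selection == "object"
  sens <- sensitivity_params(spec$sigma_s, if (obj_sel) "object" else "space")
  dp <- ddm_params(spec$theta, spec$s)
  iorp <- if (spec$ior == "space")
    ior_params("space", r = spec$r, sigma_i = spec$sigma_i)
  else ior_params("object", r = spec$r, xi = spec$xi)

  all_ids <- sort(unique(c(0L, bundle$object_registry$object_id)))
  gaze <- c((W + 1) / 2, (H + 1) / 2)
  fov_obj <- if (obj_sel) pc$masks[[1]]$labels[round(gaze[2]), round(gaze[1])] else NA_integer_
  fov_onset <- 0; fov_start <- gaze
  hx <- numeric(0); hy <- numeric(0); ht <- numeric(0)     # space-IOR history
  obj_hist <- list(foveated = if (obj_sel) fov_obj else NA_integer_,
                   last_left = stats::setNames(numeric(0), character(0)))
  V <- if (obj_sel) stats::setNames(numeric(length(all_ids)), all_ids)
       else matrix(0, H, W)
  pend_end <- NA_real_; pend_landing <- NULL; pend_target <- NA_integer_
  ev <- list(); ne <- 0L
  push <- function(row) { ne <<- ne + 1L; ev[[ne]] <<- row }
  tr_x <- numeric(T); tr_y <- numeric(T); tr_state <- character(T); tr_obj <- integer(T)

  for (t in seq_len(T)) {
    t0 <- (t - 1) * fd; t1 <- t * fd
    if (!is.na(pend_end) && pend_end >= t1 - 1e-9) {
      tr_x[t] <- gaze[1]; tr_y[t] <- gaze[2]; tr_state[t] <- "sac"; tr_obj[t] <- NA_integer_
      next
    }
    if (!is.na(pend_end)) {               # saccade lands inside this frame
      gaze <- pend_landing
      fov_obj <- if (obj_sel) pend_target else NA_integer_
      obj_hist$foveated <- fov_obj
      fov_onset <- pend_end; fov_start <- gaze
      seg_start <- max(pend_end, t0); pend_end <- NA_real_
    } else seg_start <- t0

    Fm <- pc$features[[t]]
    fr <- pc$masks[[t]]
    make_S <- function() {
      fmask <- NULL
      if (obj_sel && !is.na(fov_obj) && fov_obj > 0L) {
        key <- as.character(fov_obj)
        if (key %in% names(fr$idx)) {
          fmask <- matrix(FALSE, H, W); fmask[fr$idx[[key]]] <- TRUE
        }
      }
      sensitivity_map(gaze, sens, ppd, W, H, foveated_mask = fmask)
    }
    S <- make_S()
    I_field <- if (spec$ior == "space")
      inhibition_map_space(data.frame(x = hx, y = hy, t = ht), t, iorp, ppd, W, H)
    else NULL
    make_rates <- function() {
      if (!obj_sel) return(drift_rates_space(Fm, S, I_field))
      inh <- if (spec$ior == "object")
        stats::setNames(vapply(fr$ids, function(i)
          inhibition_object(obj_hist, t, i, iorp), numeric(1)), fr$ids)
      else I_field
      drift_rates_object(Fm, S, fr$labels, inh, ids = fr$ids, mask_idx = fr$idx)
    }
    rates <- make_rates()

    repeat {
      avail <- t1 - seg_start
      if (avail <= 1e-9) break
      nu <- min(avail / fd, 1)
      if (obj_sel) {
        keys <- as.character(fr$ids)
        V_prev <- V[keys]
        V_new <- ddm_step(V_prev, rates, nu, dp)
        cr <- detect_crossing(V_prev, V_new, spec$theta)
        if (is.null(cr)) { V[keys] <- V_new; break }
      } else {
        V_prev <- V
        V_new <- ddm_step(V_prev, rates, nu, dp)
        cr <- detect_crossing(V_prev, V_new, spec$theta)
        if (is.null(cr)) { V <- V_new; break }
      }
      t_cross <- seg_start + cr$fraction * avail
      push(list(type = "fov", t_start = fov_onset, t_end = t_cross,
                x_start = fov_start[1], y_start = fov_start[2],
                x_end = gaze[1], y_end = gaze[2],
                object_id = fov_obj, truncated = FALSE))
      if (obj_sel) {
        wid <- cr$id
        key <- as.character(wid)
        mask <- matrix(FALSE, H, W); mask[fr$idx[[key]]] <- TRUE
        landing <- saccade_landing("object", mask = mask, weights = Fm * S)
      } else {
        wid <- NA_integer_
        i <- cr$index
        landing <- c(((i - 1L) %/% H) + 1L, ((i - 1L) %% H) + 1L)
      }
      amp <- sqrt(sum((landing - gaze)^2)) / ppd
      tau <- saccade_duration(amp)
      s_end <- t_cross + tau
      push(list(type = "sac", t_start = t_cross, t_end = s_end,
                x_start = gaze[1], y_start = gaze[2],
                x_end = landing[1], y_end = landing[2],
                object_id = wid, amplitude = amp, truncated = FALSE))
      if (spec$ior == "space") {
        hx <- c(hx, landing[1]); hy <- c(hy, landing[2]); ht <- c(ht, t_cross / fd)
      }
      if (obj_sel && !is.na(fov_obj))
        obj_hist$last_left[[as.character(fov_obj)]] <- t_cross / fd
      if (obj_sel) V[] <- 0 else V[, ] <- 0
      if (s_end >= t1 - 1e-9 || s_end >= total) {
        pend_end <- s_end; pend_landing <- landing; pend_target <- wid
        obj_hist$foveated <- NA_integer_
        break
      }
      gaze <- landing
      fov_obj <- if (obj_sel) wid else NA_integer_
      obj_hist$foveated <- fov_obj
      fov_onset <- s_end; fov_start <- gaze; seg_start <- s_end
      S <- make_S()
      if (spec$ior == "space")
        I_field <- inhibition_map_space(data.frame(x = hx, y = hy, t = ht),
                                        t, iorp, ppd, W, H)
      rates <- make_rates()
    }

    in_sac <- !is.na(pend_end)
    if (!in_sac && t < T) {
      if (obj_sel) {        # pursuit via the precomputed centroid table
        if (!is.na(fov_obj) && fov_obj > 0L) {
          shift <- pc$cent[fov_obj, t + 1L, ] - pc$cent[fov_obj, t, ]
          if (!anyNA(shift))
            gaze <- clip_to_frame(gaze + shift, W, H)
        }
      } else gaze <- foveation_drift(gaze, bundle, t, "flow")
      if (spec$sigma_d > 0)
        gaze <- fixational_jitter(gaze, spec$sigma_d, ppd, W, H)
    }
    tr_x[t] <- gaze[1]; tr_y[t] <- gaze[2]
    tr_state[t] <- if (in_sac) "sac" else "fov"
    tr_obj[t] <- if (in_sac) NA_integer_ else fov_obj
  }

  if (!is.na(pend_end)) {                 # saccade spanning the video end
    last <- ev[[ne]]
    last$t_end <- total; last$truncated <- TRUE
    ev[[ne]] <- last
  } else {
    push(list(type = "fov", t_start = fov_onset, t_end = total,
              x_start = fov_start[1], y_start = fov_start[2],
              x_end = gaze[1], y_end = gaze[2],
              object_id = fov_obj, truncated = FALSE))
  }

  events <- data.frame(
    scene_id = bundle$scene_id, run_id = run_id,
    event_type = vapply(ev, `[[`, character(1), "type"),
    t_start_ms = vapply(ev, `[[`, numeric(1), "t_start"),
    t_end_ms = vapply(ev, `[[`, numeric(1), "t_end"),
    x_start_px = vapply(ev, `[[`, numeric(1), "x_start"),
    y_start_px = vapply(ev, `[[`, numeric(1), "y_start"),
    x_end_px = vapply(ev, `[[`, numeric(1), "x_end"),
    y_end_px = vapply(ev, `[[`, numeric(1), "y_end"),
    object_id = vapply(ev, function(e) as.integer(e$object_id %||% NA_integer_), integer(1)),
    amplitude_dva = vapply(ev, function(e) e$amplitude %||% NA_real_, numeric(1)),
    truncated = vapply(ev, `[[`, logical(1), "truncated"),
    stringsAsFactors = FALSE)
  events$duration_ms <- events$t_end_ms - events$t_start_ms
  trace <- data.frame(scene_id = bundle$scene_id, run_id = run_id,
                      frame = seq_len(T), t_ms = (seq_len(T) - 1) * fd,
                      x_px = tr_x, y_px = tr_y, state = tr_state,
                      object_id = tr_obj, stringsAsFactors = FALSE)
  if (!obj_sel) {    # position-only scanpath: object ids via the 1-dva majority rule
    fovs <- events$event_type == "fov"
    events$object_id[fovs] <- assign_objects(trace, bundle, events[fovs, ])
  }
  structure(list(events = events, trace = if (keep_trace) trace else NULL),
            class = "scanpath")
}

#' @export
print.scanpath <- function(x, ...) {
  n_f <- sum(x$events$event_type == "fov")
  n_s <- sum(x$events$event_type == "sac")
  cat(sprintf("<scanpath> %d foveations, %d saccades, %.0f ms\n",
              n_f, n_s, max(x$events$t_end_ms)))
  invisible(x)
}

#' Simulate a batch of scanpaths
#'
#' Runs `n_runs` independently seeded scanpaths per scene (12 by default,
#' mirroring the number of observers the reference statistics are built
#' from), with reproducible per-(scene, run) sub-seeds derived from
#' `base_seed`.
#'
#' @param bundles A `scene_bundle` or list of them.
#' @param spec A [model_spec()].
#' @param n_runs Scanpaths per scene (default 12).
#' @param base_seed Integer base seed.
#' @param keep_trace Attach per-frame traces as attribute `"traces"`.
#' @return Combined event table (rows tagged by `scene_id` and `run_id`).
#' @export
run_batch <- function(bundles, spec, n_runs = 12L, base_seed = 1L,
                      keep_trace = FALSE) {
  if (inherits(bundles, "scene_bundle")) bundles <- list(bundles)
  stopifnot(n_runs >= 1)
  out <- list(); traces <- list(); k <- 0L
  for (i in seq_along(bundles)) {
    pc <- scene_precompute(bundles[[i]], spec)
    for (j in seq_len(n_runs)) {
      k <- k + 1L
      sp <- simulate_scanpath(bundles[[i]], spec,
                              seed = derive_seed(base_seed, i * 1009L + j),
                              run_id = j, precomp = pc, keep_trace = keep_trace)
      out[[k]] <- sp$events
      if (keep_trace) traces[[k]] <- sp$trace
    }
  }
  events <- do.call(rbind, out)
  if (keep_trace) attr(events, "traces") <- do.call(rbind, traces)
  events
}
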