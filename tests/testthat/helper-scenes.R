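# Small programmatic fixtures shared across test files.

# Fast unit-test scene: 40 x 30 px (20 x 15 dva), 60 frames, 2 objects.
tiny_scene <- function(seed = 1L, noise_sd = 0, n_frames = 60L,
                       vx = c(0.2, 0), vy = c(0, 0)) {
  obj <- data.frame(shape = c("ellipse", "rectangle"),
                    width_px = c(10, 8), height_px = c(8, 6),
                    x0 = c(12, 30), y0 = c(10, 22),
                    vx = vx, vy = vy,
                    feature_amplitude = c(0.8, 0.6),
                    feature_width_px = c(4, 3))
  synth_scene(synth_spec(width = 40L, height = 30L, n_frames = n_frames,
                         objects = obj, noise_sd = noise_sd, seed = seed))
}

# Two identical objects mirror-symmetric about the frame centre.
symmetric_scene <- function(seed = 1L, n_frames = 90L) {
  obj <- data.frame(shape = c("ellipse", "ellipse"),
                    width_px = c(8, 8), height_px = c(8, 8),
                    x0 = c(12, 29), y0 = c(15.5, 15.5),
                    vx = c(0, 0), vy = c(0, 0),
                    feature_amplitude = c(0.8, 0.8),
                    feature_width_px = c(4, 4))
  synth_scene(synth_spec(width = 40L, height = 30L, n_frames = n_frames,
                         objects = obj, noise_sd = 0, seed = seed))
}

# One static, strongly salient object off-centre; noise-free.
single_object_scene <- function(seed = 1L, n_frames = 90L) {
  obj <- data.frame(shape = "ellipse", width_px = 10, height_px = 8,
                    x0 = 28, y0 = 10, vx = 0, vy = 0,
                    feature_amplitude = 0.9, feature_width_px = 5)
  synth_scene(synth_spec(width = 40L, height = 30L, n_frames = n_frames,
                         objects = obj, background_level = 0.05,
                         noise_sd = 0, seed = seed))
}

# Minimal hand-built event table row.
make_event <- function(type, t0, t1, x0 = 0, y0 = 0, x1 = 0, y1 = 0,
                       object_id = NA_integer_, amp = NA_real_,
                       scene = "s", run = 1L) {
  data.frame(scene_id = scene, run_id = run, event_type = type,
             t_start_ms = t0, t_end_ms = t1, x_start_px = x0, y_start_px = y0,
             x_end_px = x1, y_end_px = y1, object_id = object_id,
             amplitude_dva = amp, truncated = FALSE, duration_ms = t1 - t0,
             stringsAsFactors = FALSE)
}
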