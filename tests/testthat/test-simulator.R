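test_that("model variants wire selection, features and IOR as published", {
  s <- model_spec("S.ll")
  expect_equal(c(s$selection, s$source, s$ior), c("space", "lowlevel", "space"))
  expect_equal(model_spec("S.hl")$source, "highlevel")
  o <- model_spec("O.ll")
  expect_equal(c(o$selection, o$ior), c("object", "object"))
  cb <- model_spec("O.cb")
  expect_equal(c(cb$source, cb$ior), c("none", "object"))
  m <- model_spec("M.ll")
  expect_equal(c(m$selection, m$ior), c("object", "space"))
  expect_equal(model_spec("O.ll", theta = 1.5)$theta, 1.5)
  expect_error(model_spec("O.ll", xi = 2), "xi")
})

test_that("every simulated scanpath conserves time and stays in frame", {
  b <- tiny_scene(noise_sd = 0.02)
  total <- b$n_frames / b$fps * 1000
  for (v in c("S.ll", "O.ll", "M.ll", "O.cb")) {
    sp <- simulate_scanpath(b, model_spec(v), seed = 11)
    ev <- sp$events
    expect_equal(sum(ev$duration_ms), total, tolerance = 1e-9)
    # events tile the duration: each starts where the previous ended
    expect_equal(ev$t_start_ms[-1], ev$t_end_ms[-nrow(ev)], tolerance = 1e-9)
    expect_true(all(ev$event_type[c(TRUE, FALSE)] == "fov"))
    expect_equal(ev$t_start_ms[1], 0)
    expect_true(all(sp$trace$x_px >= 1 & sp$trace$x_px <= b$width_px))
    expect_true(all(sp$trace$y_px >= 1 & sp$trace$y_px <= b$height_px))
  }
})

test_that("the first foveation starts at the frame centre at t = 0", {
  b <- tiny_scene()
  sp <- simulate_scanpath(b, model_spec("O.ll"), seed = 2)
  first <- sp$events[1, ]
  expect_equal(first$event_type, "fov")
  expect_equal(first$t_start_ms, 0)
  expect_equal(c(first$x_start_px, first$y_start_px),
               c((b$width_px + 1) / 2, (b$height_px + 1) / 2))
})

test_that("simulation is deterministic given the seed", {
  b <- tiny_scene(noise_sd = 0.02)
  s1 <- simulate_scanpath(b, model_spec("O.ll"), seed = 42)
  s2 <- simulate_scanpath(b, model_spec("O.ll"), seed = 42)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$trace, s2$trace)
  s3 <- simulate_scanpath(b, model_spec("O.ll"), seed = 43)
  expect_false(identical(s1$events, s3$events))
})

test_that("a noiseless race saccades to the strongest object at theta/mu", {
  b <- single_object_scene()
  spec <- model_spec("O.ll", theta = 1.5, s = 0, sigma_s = 15, sigma_d = 0)
  sp <- simulate_scanpath(b, spec, seed = 1)
  ev <- sp$events
  # first saccade goes to the salient object
  expect_equal(ev$object_id[ev$event_type == "fov"][2], 1L)
  # closed-form decision time: everything is static until the first saccade
  Fm <- combined_feature_map(b, 1, spec$source, spec$cb_params)
  S <- sensitivity_map(c((b$width_px + 1) / 2, (b$height_px + 1) / 2),
                       sensitivity_params(spec$sigma_s, "object"),
                       b$px_per_dva, b$width_px, b$height_px,
                       foveated_mask = matrix(FALSE, b$height_px, b$width_px))
  inh <- c(`0` = 0, `1` = 0)
  mu <- drift_rates_object(Fm, S, b$objects[, , 1], inh)
  fd <- 1000 / b$fps
  expect_equal(ev$duration_ms[1], spec$theta / max(mu) * fd, tolerance = 1e-6)
})

test_that("object-mode saccades land inside the target mask at decision time", {
  b <- tiny_scene(noise_sd = 0.02, n_frames = 120L)
  sp <- simulate_scanpath(b, model_spec("O.ll", theta = 1), seed = 9)
  ev <- sp$events
  fd <- 1000 / b$fps
  idx <- which(ev$event_type == "sac")
  for (k in idx) {
    if (k + 1 > nrow(ev)) next
    target <- ev$object_id[k + 1]
    frame <- min(floor(ev$t_start_ms[k] / fd) + 1, b$n_frames)
    lab <- b$objects[round(ev$y_end_px[k]), round(ev$x_end_px[k]), frame]
    expect_equal(as.integer(lab), as.integer(target))
  }
})

test_that("the centre-bias-only variant ignores the feature field entirely", {
  b <- tiny_scene(noise_sd = 0.02)
  b2 <- b
  set.seed(99)
  b2$features <- pmin(pmax(b2$features +
    array(rnorm(length(b2$features), 0, 0.2), dim(b2$features)), 0), 1)
  s1 <- simulate_scanpath(b, model_spec("O.cb"), seed = 5)
  s2 <- simulate_scanpath(b2, model_spec("O.cb"), seed = 5)
  expect_identical(s1$events, s2$events)
  # while the feature-driven variant does react
  o1 <- simulate_scanpath(b, model_spec("O.ll"), seed = 5)
  o2 <- simulate_scanpath(b2, model_spec("O.ll"), seed = 5)
  expect_false(identical(o1$events, o2$events))
})

test_that("batches are reproducible and explore distinct first targets", {
  b <- symmetric_scene()
  spec <- model_spec("O.ll", theta = 1, s = 0.25)
  ev <- run_batch(b, spec, n_runs = 12, base_seed = 3)
  expect_identical(ev, run_batch(b, spec, n_runs = 12, base_seed = 3))
  firsts <- sapply(split(ev, ev$run_id), function(d) {
    f <- d$object_id[d$event_type == "fov" & d$object_id > 0]
    if (length(f)) f[1] else NA_integer_
  })
  # the symmetric race should not collapse onto a single target
  expect_gte(length(unique(stats::na.omit(firsts))), 2)
  ev1 <- run_batch(b, spec, n_runs = 1, base_seed = 3)
  expect_equal(length(unique(ev1$run_id)), 1)
})

test_that("a saccade spanning the video end is truncated and flagged", {
  # tiny threshold + huge noise force saccades until the very end
  b <- tiny_scene(n_frames = 30L, noise_sd = 0.02)
  found <- FALSE
  for (seed in 1:20) {
    ev <- simulate_scanpath(b, model_spec("O.ll", theta = 0.35, s = 0.3),
                            seed = seed)$events
    if (any(ev$truncated)) {
      last <- ev[nrow(ev), ]
      expect_equal(last$t_end_ms, b$n_frames / b$fps * 1000)
      expect_equal(last$event_type, "sac")
      found <- TRUE
      break
    }
  }
  expect_true(found)
})
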