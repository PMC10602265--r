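test_that("synthetic scenes obey constant-velocity kinematics and label construction", {
  obj <- data.frame(shape = "ellipse", width_px = 8, height_px = 8,
                    x0 = 10, y0 = 15, vx = 1, vy = 0,
                    feature_amplitude = 0.8, feature_width_px = 3)
  b <- synth_scene(synth_spec(width = 40L, height = 30L, n_frames = 10L,
                              objects = obj, noise_sd = 0, seed = 1))
  reg <- b$object_registry
  expect_equal(reg$cx[reg$frame == 10] - reg$cx[reg$frame == 1], 9)
  expect_equal(reg$cy[reg$frame == 10], reg$cy[reg$frame == 1])

  b2 <- tiny_scene()
  expect_true(all(unique(as.integer(b2$objects)) %in% 0:2))

  obj3 <- data.frame(shape = "ellipse", width_px = 8, height_px = 8,
                     x0 = 20, y0 = 15, vx = 0, vy = 0,
                     feature_amplitude = 0.8, feature_width_px = 3)
  b3 <- synth_scene(synth_spec(width = 40L, height = 30L, n_frames = 5L,
                               objects = obj3, background_level = 0.1,
                               noise_sd = 0, seed = 1))
  expect_lte(max(b3$features), 0.9 + 1e-12)
  expect_gte(min(b3$features), 0.1 - 1e-12)
})

test_that("flow matches object velocity inside masks and is zero elsewhere", {
  b <- tiny_scene(vx = c(0.5, -0.25), vy = c(0.1, 0))
  lab <- b$objects[, , 3]
  fx <- b$flow[, , 3, 1]; fy <- b$flow[, , 3, 2]
  expect_true(all(fx[lab == 1L] == 0.5) && all(fy[lab == 1L] == 0.1))
  expect_true(all(fx[lab == 2L] == -0.25) && all(fy[lab == 2L] == 0))
  expect_true(all(fx[lab == 0L] == 0) && all(fy[lab == 0L] == 0))
})

test_that("generation is deterministic and rejects off-frame objects", {
  expect_identical(tiny_scene(seed = 7, noise_sd = 0.05),
                   tiny_scene(seed = 7, noise_sd = 0.05))
  off <- data.frame(shape = "ellipse", width_px = 4, height_px = 4,
                    x0 = -50, y0 = -50, vx = 0, vy = 0,
                    feature_amplitude = 0.5, feature_width_px = 2)
  expect_error(synth_scene(synth_spec(width = 40L, height = 30L, n_frames = 5L,
                                      objects = off, seed = 1)),
               "outside the frame")
})

test_that("HDF5 round trip is the identity and load validates its inputs", {
  b <- tiny_scene(seed = 3, noise_sd = 0.05)
  f <- tempfile(fileext = ".h5")
  save_scene(b, f)
  b2 <- load_scene(f)
  expect_identical(b2$features, b$features)
  expect_identical(b2$objects, b$objects)
  expect_identical(b2$flow, b$flow)
  expect_equal(b2$object_registry, b$object_registry)
  expect_equal(b2$fps, b$fps)
  expect_equal(b2$px_per_dva, b$px_per_dva)
  expect_identical(b2$scene_id, b$scene_id)

  # archive missing the flow dataset
  f2 <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(f2)
  rhdf5::h5write(b$features, f2, "features")
  rhdf5::h5write(b$objects, f2, "objects")
  expect_error(load_scene(f2), "flow missing")

  # out-of-range features
  f3 <- tempfile(fileext = ".h5")
  bad <- b
  bad$features[1, 1, 1] <- 1.2
  rhdf5::h5createFile(f3)
  rhdf5::h5write(bad$features, f3, "features")
  rhdf5::h5write(bad$objects, f3, "objects")
  rhdf5::h5write(bad$flow, f3, "flow")
  expect_error(load_scene(f3), "range")
  unlink(c(f, f2, f3))
})

test_that("validate_scene reports invariant violations without raising", {
  b <- tiny_scene()
  expect_length(validate_scene(b), 0)

  b_bad <- b
  b_bad$object_registry$cx[1] <- b_bad$object_registry$cx[1] + 1
  expect_match(validate_scene(b_bad), "centroid", all = FALSE)

  # more than 100 distinct object ids
  b_ids <- b
  lab <- b_ids$objects
  m <- lab[, , 1]
  m[which(m == 0L)[1:101]] <- 101:201
  lab[, , 1] <- m
  b_ids$objects <- lab
  b_ids$object_registry <- scanpathsim:::build_registry(lab)
  expect_match(validate_scene(b_ids), "exceeds 100 object IDs", all = FALSE)

  b_feat <- b
  b_feat$features[2, 2, 2] <- 1.5
  expect_match(validate_scene(b_feat), "outside \\[0, 1\\]", all = FALSE)
})

test_that("the control transform is an involution that preserves motion direction", {
  b <- tiny_scene(seed = 5, noise_sd = 0.03, vx = c(0.4, 0), vy = c(0, 0.2))
  tb <- transform_scene(b)
  back <- transform_scene(tb)
  expect_identical(back$features, b$features)
  expect_identical(back$objects, b$objects)
  expect_identical(back$flow, b$flow)

  # frame 1 of the output is the doubly mirrored last input frame
  H <- b$height_px; W <- b$width_px
  expect_identical(tb$features[, , 1],
                   b$features[rev(seq_len(H)), rev(seq_len(W)), b$n_frames])

  # object 1 moves right in the original; after time reversal + double
  # mirroring the two sign flips cancel and it still moves right
  reg <- tb$object_registry
  r1 <- reg[reg$object_id == 1L, ]
  r1 <- r1[order(r1$frame), ]
  expect_gt(r1$cx[nrow(r1)], r1$cx[1])
  # stored flow components are unchanged inside the mask
  lab <- tb$objects[, , 3]
  expect_true(all(tb$flow[, , 3, 1][lab == 1L] == 0.4))
})
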