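test_that("event filters drop short foveations and microsaccades", {
  tab <- rbind(make_event("fov", 0, 30),
               make_event("fov", 30, 64),
               make_event("sac", 64, 80, amp = 0.4),
               make_event("sac", 80, 100, amp = 0.5),
               make_event("fov", 100, 133.3))
  out <- filter_events(tab)
  expect_equal(out$duration_ms[out$event_type == "fov"], c(34, 33.3))
  expect_equal(out$amplitude_dva[out$event_type == "sac"], 0.5)
  empty <- tab[0, ]
  expect_equal(nrow(filter_events(empty)), 0)
})

test_that("gaze-to-object assignment uses the 1-dva dilation and majority rule", {
  b <- tiny_scene(vx = c(0, 0), vy = c(0, 0))   # object 1 ellipse at (12, 10)
  lab <- b$objects[, , 1]
  # a gaze 0.8 dva (1.6 px) left of the mask boundary -> still the object
  left_edge <- min(which(lab == 1L, arr.ind = TRUE)[, 2])
  expect_equal(object_at_gaze(b, 1, left_edge - 1.6, 10), 1L)
  # 1.5 dva (3 px) away from every mask -> background
  expect_equal(object_at_gaze(b, 1, left_edge - 3.2, 2), 0L)
  # inside the mask -> trivially the object
  expect_equal(object_at_gaze(b, 1, 12, 10), 1L)

  # majority rule: 6 frames on object 1, 4 on background
  fd <- 1000 / b$fps
  tr <- data.frame(frame = 1:10, t_ms = (0:9) * fd,
                   x_px = c(rep(12, 6), rep(39, 4)),
                   y_px = c(rep(10, 6), rep(29, 4)),
                   state = "fov")
  ev <- data.frame(t_start_ms = 0, t_end_ms = 10 * fd)
  expect_equal(assign_objects(tr, b, ev), 1L)
})

test_that("functional categories follow the detection/inspection/return rules", {
  expect_equal(categorize_foveations(c(0L, 3L, 3L, 5L, 3L)),
               c("Background", "Detection", "Inspection", "Detection", "Return"))
  expect_equal(categorize_foveations(c(0L, 0L, 0L)), rep("Background", 3))
  expect_equal(categorize_foveations(c(2L, 0L, 2L)),
               c("Detection", "Background", "Return"))
  # each object is detected at most once per scanpath
  set.seed(1)
  for (i in 1:20) {
    ids <- sample(0:3, 15, replace = TRUE)
    cats <- categorize_foveations(ids)
    expect_equal(length(cats), length(ids))
    det <- ids[cats == "Detection"]
    expect_equal(anyDuplicated(det), 0)
  }
})

test_that("the KS statistic matches brute-force enumeration and stats::ks.test", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(ks_statistic(c(1, 2), c(1, 3)), 0.5)
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(40); b <- rnorm(35, 0.5)
    expect_equal(ks_statistic(a, b),
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
    expect_equal(ks_statistic(a, b), ks_statistic(b, a))
  }
  expect_error(ks_statistic(numeric(0), 1), "empty")
})

test_that("fitness is the negative mean of the two KS distances", {
  # construct tables whose pooled KS distances are known: amplitudes fully
  # disjoint (d_SA = 1), durations identical (d_FD = 0)
  sim <- rbind(make_event("fov", 0, 100), make_event("sac", 100, 120, amp = 1),
               make_event("fov", 120, 300), make_event("sac", 300, 330, amp = 2))
  ref <- rbind(make_event("fov", 0, 100), make_event("sac", 100, 120, amp = 7),
               make_event("fov", 120, 300), make_event("sac", 300, 330, amp = 9))
  f <- fitness(sim, ref)
  expect_equal(as.numeric(f), -0.5)
  expect_equal(attr(f, "d_SA"), 1)
  expect_equal(attr(f, "d_FD"), 0)
  # identity: a table against itself scores the maximum 0
  expect_equal(as.numeric(fitness(sim, sim)), 0)
  # arithmetic of the definition
  expect_equal(-(0.2 + 0.1) / 2, -0.15)
  # bounded in [-1, 0]
  expect_gte(as.numeric(f), -1)
  expect_lte(as.numeric(f), 0)
})

test_that("relative saccade angles, return saccades and binned durations", {
  # scanpath with saccades (1,0) then (-1,0): phi = 180
  s1 <- rbind(make_event("fov", 0, 200, 10, 10, 10, 10),
              make_event("sac", 200, 230, 10, 10, 20, 10, amp = 5),
              make_event("fov", 230, 500, 20, 10, 20, 10),
              make_event("sac", 500, 530, 20, 10, 10, 10, amp = 5))
  st <- sequential_stats(s1)
  expect_equal(st$pairs$phi, 180)
  expect_equal(st$n_pairs, 1)
  expect_equal(st$frac_gt135, 1)
  # |phi| > 178 with amplitude difference 0 -> return saccade
  expect_equal(st$return_ratio, 1)
  # preceding foveation of the second saccade
  expect_equal(st$pairs$prec_fd_ms, 270)

  # (1,0) then (0,1): phi = +90 under the documented convention
  # (positive = rotation from +x toward +y, y pointing downward)
  s2 <- rbind(make_event("fov", 0, 100),
              make_event("sac", 100, 130, 10, 10, 20, 10, amp = 5),
              make_event("fov", 130, 400, 20, 10, 20, 10),
              make_event("sac", 400, 430, 20, 10, 20, 20, amp = 5))
  expect_equal(sequential_stats(s2)$pairs$phi, 90)

  # 179-degree pair: return iff the amplitude difference is below 1.5 dva
  mk179 <- function(amp2) {
    v2 <- c(cos(179 * pi / 180), sin(179 * pi / 180)) * amp2 * 2
    rbind(make_event("fov", 0, 100),
          make_event("sac", 100, 130, 10, 15, 20, 15, amp = 5),
          make_event("fov", 130, 400, 20, 15, 20, 15),
          make_event("sac", 400, 430, 20, 15, 20 + v2[1], 15 + v2[2],
                     amp = amp2))
  }
  expect_equal(sequential_stats(mk179(5 - 0.5))$return_ratio, 1)
  expect_equal(sequential_stats(mk179(5 - 2.0))$return_ratio, 0)
  expect_equal(abs(sequential_stats(mk179(4.5))$pairs$phi), 179)

  # degenerate input: empty summaries, no error
  st0 <- sequential_stats(s1[1:2, ])
  expect_equal(st0$n_pairs, 0)

  # histogram has 30 bins of 12 degrees, circularly smoothed medians exist
  expect_equal(nrow(st$angle_hist), 30)
  expect_equal(sum(st$angle_hist$count), 1)
  expect_equal(nrow(st$binned_fd), 30)
})

test_that("object dwell regression, return times and first detections", {
  mk <- function(run, scene = "s1") {
    rbind(make_event("fov", 0, 500, object_id = 1L, scene = scene, run = run),
          make_event("sac", 500, 530, amp = 5, scene = scene, run = run),
          make_event("fov", 530, 1000, object_id = 2L, scene = scene, run = run),
          make_event("sac", 1000, 1030, amp = 5, scene = scene, run = run),
          make_event("fov", 1030, 1500, object_id = 1L, scene = scene, run = run))
  }
  tab <- mk(1L)
  # identical sim and ref: slope 1, intercept 0, r^2 = 1
  os <- object_stats(rbind(mk(1L), mk(2L)), rbind(mk(1L), mk(2L)))
  expect_equal(os$m, 1)
  expect_equal(os$y0, 0, tolerance = 1e-9)
  expect_equal(os$r2, 1)
  expect_equal(os$first_detection_agreement, 1)

  # A@[0,500], B@[530,1000], A@[1030,...]: one return to A after 530 ms
  rt <- scanpathsim:::table_object_returns(tab)
  expect_equal(rt$ratio, 1 / 2)
  expect_equal(rt$median_ms, 1030 - 500)
  expect_equal(rt$times_ms, 530)

  # worked return-time example: A@[0,500], B@[600,1000], A@[1100,...]
  tab2 <- rbind(make_event("fov", 0, 500, object_id = 1L),
                make_event("sac", 500, 600, amp = 5),
                make_event("fov", 600, 1000, object_id = 2L),
                make_event("sac", 1000, 1100, amp = 5),
                make_event("fov", 1100, 1500, object_id = 1L))
  expect_equal(scanpathsim:::table_object_returns(tab2)$times_ms, 600)

  # single run: first non-background foveation defines the first detection
  tab3 <- rbind(make_event("fov", 0, 300, object_id = 0L),
                make_event("sac", 300, 330, amp = 5),
                make_event("fov", 330, 800, object_id = 4L))
  fd <- scanpathsim:::modal_first_detection(tab3)
  expect_equal(fd$first_object, 4L)
})

test_that("category time courses are normalised over foveation time only", {
  tab <- rbind(make_event("fov", 0, 250, object_id = 0L),
               make_event("sac", 250, 280, amp = 5),
               make_event("fov", 280, 600, object_id = 1L))
  tc <- category_timecourse(tab, bin_ms = 100)
  sums <- tapply(tc$proportion, tc$bin_start_ms, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # bin [200, 300): 50 ms Background + 20 ms Detection, saccade time excluded
  expect_equal(tc$proportion[tc$bin_start_ms == 200 &
                             tc$category == "Background"], 50 / 70)
  expect_equal(tc$proportion[tc$bin_start_ms == 200 &
                             tc$category == "Detection"], 20 / 70)
  # all-background input
  tabb <- make_event("fov", 0, 400, object_id = 0L)
  tcb <- category_timecourse(tabb, bin_ms = 100)
  expect_true(all(tcb$proportion[tcb$category == "Background"] == 1))
})

test_that("the scene control transform pushes off-centre foveations to background", {
  b <- single_object_scene(n_frames = 30L)   # object well off-centre at (28, 10)
  tb <- transform_scene(b)
  fd <- 1000 / b$fps
  # a scanpath parked on the object, kept unchanged across the transform
  tr <- data.frame(frame = 1:30, t_ms = (0:29) * fd,
                   x_px = 28, y_px = 10, state = "fov")
  ev <- data.frame(t_start_ms = 0, t_end_ms = 30 * fd)
  expect_equal(assign_objects(tr, b, ev), 1L)
  expect_equal(assign_objects(tr, tb, ev), 0L)
})
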