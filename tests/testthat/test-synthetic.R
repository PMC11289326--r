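test_that("seated protocols honor the 3 + 2x8 instruction structure", {
  sch <- make_protocol("seated_chinrest", seed = 1)
  expect_equal(nrow(sch), 19)
  expect_equal(sch$label[c(1, 10, 19)], rep("center", 3))
  counts <- table(sch$label)
  expect_equal(unname(counts[["center"]]), 3)
  expect_true(all(counts[names(counts) != "center"] == 2))
  expect_equal(sch$onset_s, (0:18) * 12)
  # two seeds: same multiset, different order
  sch2 <- make_protocol("seated_chinrest", seed = 2)
  expect_equal(sort(sch2$label), sort(sch$label))
  expect_false(identical(sch2$label, sch$label))
  # walking: two epochs
  w <- make_protocol("walking", seed = 1)
  expect_equal(nrow(w), 2)
  expect_equal(unique(w$label), "bullseye")
})

test_that("chinrest track geometry follows the physical layout", {
  sc <- synthetic_scenario("seated_chinrest", "tobii3", tremor_px = 0,
                           seed = 3)
  ses <- simulate_session(sc)
  tr <- ses$track
  # static: every label constant over time
  for (lb in c("center", "top", "left"))
    expect_equal(length(unique(tr$x_px[tr$label == lb])), 1)
  # instructed-dot offset = pixel projection of the physical 268-mm ring
  # radius (the closed-form 15-degree eccentricity), shifted vertically
  # by the camera pitch
  cam <- sc$camera
  cx <- cam$width_px / 2; cy <- cam$height_px / 2
  pitch_dy <- -deg_to_px(cam$pitch_deg, cam)
  right <- tr[tr$label == "right" & tr$frame == 0, ]
  expect_equal(right$x_px - cx,
               deg_to_px(atan(268 / 1000) * 180 / pi, cam),
               tolerance = 1e-9)
  expect_equal(right$y_px, cy + pitch_dy, tolerance = 1e-9)
})

test_that("free-head steady state re-centers the instructed dot", {
  sc <- synthetic_scenario("seated_free", "tobii3", tremor_px = 0,
                           head_recenter = 1, seed = 8)
  ses <- simulate_session(sc)
  cam <- sc$camera
  # well after an onset, the instructed dot sits at the image center
  k <- 5
  lb <- ses$schedule$label[k]
  f <- (ses$schedule$onset_s[k] + 8) * 25
  row <- ses$track[ses$track$label == lb & ses$track$frame == f, ]
  expect_equal(c(row$x_px, row$y_px),
               c(cam$width_px / 2, cam$height_px / 2), tolerance = 1e-6)
})

test_that("exactness: no bias, no noise, no blinks gives zero error", {
  sc <- synthetic_scenario("seated_chinrest", "tobii3", bias_deg = 0,
                           noise_sd_deg = 0, blink_rate_hz = 0,
                           tremor_px = 0, seed = 4)
  ses <- simulate_session(sc)
  frames <- frame_average(filter_recording(ses$recording))
  iv <- seated_intervals(ses$schedule)
  for (i in c(1, 7, 19)) {
    r <- interval_accuracy(frames, ses$track, sc$camera, iv[i, ])
    expect_equal(r$accuracy_deg, 0, tolerance = 1e-9)
  }
})

test_that("injected bias is recovered through the full pipeline", {
  sc <- synthetic_scenario("seated_chinrest", "tobii3", bias_deg = 2,
                           noise_sd_deg = 0, blink_rate_hz = 0, seed = 5)
  ses <- simulate_session(sc)
  frames <- frame_average(filter_recording(ses$recording))
  iv <- seated_intervals(ses$schedule)
  centers <- which(iv$label == "center")
  for (i in centers) {
    r <- interval_accuracy(frames, ses$track, sc$camera, iv[i, ])
    # center target sits ~1 degree off-axis (pitch), so the pixel-space
    # bias subtends within a hair of its nominal center-referred angle
    expect_equal(r$accuracy_deg, 2, tolerance = 0.01)
    expect_equal(r$bias_deg, 2, tolerance = 0.01)
  }
})

test_that("blink statistics match the injected process", {
  sc <- synthetic_scenario("seated_chinrest", "tobii2",
                           blink_rate_hz = 0.2, seed = 19)
  ses <- simulate_session(sc)
  pre <- missing_fraction(frame_average(ses$recording))
  post <- missing_fraction(frame_average(filter_recording(ses$recording)))
  expected_pct <- 100 * ses$truth$blink_time_s / ses$truth$span_s
  expect_lt(abs(pre - expected_pct), 3)
  expect_lt(post, pre)
  # no blinks -> no missing frames
  sc0 <- synthetic_scenario("seated_chinrest", "tobii2",
                            blink_rate_hz = 0, seed = 19)
  ses0 <- simulate_session(sc0)
  expect_equal(missing_fraction(frame_average(ses0$recording)), 0)
})

test_that("identical scenarios reproduce bit-identical sessions", {
  sc <- synthetic_scenario("walking", "tobii2", seed = 33)
  a <- simulate_session(sc)
  b <- simulate_session(sc)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(as.data.frame(a$track), as.data.frame(b$track))
  expect_identical(a$schedule$label, b$schedule$label)
  # and rendered frames too
  fa <- render_session_frames(sc, a$schedule, 100)
  fb <- render_session_frames(sc, b$schedule, 100)
  expect_identical(fa, fb)
})

test_that("target speed orders chinrest < free-head < walking", {
  speeds <- sapply(c("seated_chinrest", "seated_free", "walking"),
                   function(cond) {
    sc <- synthetic_scenario(cond, "tobii2", seed = 12)
    ses <- simulate_session(sc)
    iv <- if (cond == "walking") walking_intervals(ses$track)[1, ]
          else seated_intervals(ses$schedule)[5, ]
    target_speed(ses$track, sc$camera, iv)
  })
  expect_lt(speeds[1], speeds[2])
  expect_lt(speeds[2], speeds[3])
  # walking an order of magnitude above seated free-head
  expect_gt(speeds[3] / speeds[2], 5)
})

test_that("estimated VD recovers the scenario camera exactly", {
  for (dev in c("tobii2", "tobii3")) {
    cam <- device_profile(dev)$camera
    D <- 1000
    d <- D * 400 / cam$vd_px  # simulated on-wall calibration offsets
    cal <- calibration_measurement(D, rep(d, 4))
    expect_equal(estimate_vd(cal), cam$vd_px, tolerance = 1e-12)
  }
})

test_that("rendered seated frames are recoverable by the vision module", {
  sc <- synthetic_scenario("seated_chinrest", "tobii3", tremor_px = 0,
                           seed = 2)
  sch <- make_protocol("seated_chinrest", 2)
  frame <- render_session_frames(sc, sch, 0)[[1]]
  det <- detect_dots(frame, radius_range = c(5, 16))
  tr <- simulate_target_track(sc, sch)
  m <- merge(det[det$detected, ], tr[tr$frame == 0, ], by = "label")
  expect_equal(nrow(m), 9)
  err <- sqrt((m$x_px.x - m$x_px.y)^2 + (m$y_px.x - m$y_px.y)^2)
  expect_lt(max(err), 1)
})

test_that("a dot out of frame is undetected without harming the others", {
  # the 50-Hz device's 12-degree camera pitch pushes the top dot off the
  # top edge of the image
  sc <- synthetic_scenario("seated_chinrest", "tobii2", tremor_px = 0,
                           seed = 2)
  sch <- make_protocol("seated_chinrest", 2)
  tr <- simulate_target_track(sc, sch)
  f0 <- tr[tr$frame == 0, ]
  expect_false(f0$detected[f0$label == "top"])
  expect_equal(sum(f0$detected), 8)
  frame <- render_session_frames(sc, sch, 0)[[1]]
  det <- detect_dots(frame, radius_range = c(5, 16))
  expect_false(det$detected[det$label == "top"])
  expect_equal(sum(det$detected), 8)
})

test_that("walking frames support the vanishing-point prior", {
  sc <- synthetic_scenario("walking", "tobii3", seed = 7)
  sch <- make_protocol("walking", 7)
  tr <- simulate_target_track(sc, sch)
  f <- 200
  frame <- render_session_frames(sc, sch, f)[[1]]
  b <- tr[tr$frame == f & tr$label == "bullseye", ]
  vp <- carpet_vanishing_point(frame)
  expect_lt(sqrt((vp$x_px - b$x_px)^2 + (vp$y_px - b$y_px)^2), 5)
  obs <- locate_bullseye(frame, vp, radius_range = c(5, 70),
                         frame_index = f)
  expect_true(obs$detected)
  expect_lt(sqrt((obs$x_px - b$x_px)^2 + (obs$y_px - b$y_px)^2), 2)
})

test_that("scenario validation rejects inconsistent inputs", {
  expect_error(synthetic_scenario("seated_chinrest", head_recenter = 2))
  expect_error(synthetic_scenario("walking", walk_duration_s = 5))
  sc <- synthetic_scenario("walking", seed = 1)
  sch <- make_protocol("seated_chinrest", 1)
  expect_error(simulate_target_track(sc, sch), "bullseye")
})
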