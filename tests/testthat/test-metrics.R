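cam_t2 <- camera_model(vd_px = 1132.4)

static_case <- function(gaze_xy, n = 250, cam = cam_t2,
                        target_xy = c(960, 540)) {
  frames <- data.frame(frame = 0:(n - 1), t = (0:(n - 1)) / 25,
                       x_px = gaze_xy[1], y_px = gaze_xy[2],
                       missing = FALSE)
  class(frames) <- c("frame_gaze", "data.frame")
  track <- target_track(data.frame(frame = 0:(n - 1), label = "center",
                                   x_px = target_xy[1], y_px = target_xy[2],
                                   detected = TRUE))
  interval <- data.frame(start_t = 0, end_t = n / 25, label = "center",
                         kind = "seated")
  list(frames = frames, track = track, interval = interval)
}

test_that("interval accuracy: exact cases", {
  cs <- static_case(c(960, 540))
  r <- interval_accuracy(cs$frames, cs$track, cam_t2, cs$interval)
  expect_equal(r$accuracy_deg, 0)
  expect_equal(r$n_frames_valid, 250)
  # constant 400-px offset: closed form atan(400 / VD)
  cs <- static_case(c(1360, 540))
  r <- interval_accuracy(cs$frames, cs$track, cam_t2, cs$interval)
  expect_equal(r$accuracy_deg, atan(400 / 1132.4) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(r$accuracy_deg, r$bias_deg, tolerance = 1e-12)
})

test_that("isotropic noise yields the Rayleigh mean angular distance", {
  set.seed(1234)
  sigma <- 1
  means <- replicate(40, {
    cs <- make_recovery_case(cam_t2, 0, sigma)
    interval_accuracy(cs$frames, cs$track, cam_t2, cs$interval)$accuracy_deg
  })
  expected <- sigma * sqrt(pi / 2)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se + 0.01)
})

test_that("bias cancels symmetric error while accuracy does not", {
  n <- 250
  frames <- data.frame(frame = 0:(n - 1), t = (0:(n - 1)) / 25,
                       x_px = 960 + c(-400, 400), y_px = 540,
                       missing = FALSE)
  class(frames) <- c("frame_gaze", "data.frame")
  cs <- static_case(c(960, 540))
  b <- interval_bias(frames, cs$track, cam_t2, cs$interval)
  a <- interval_accuracy(frames, cs$track, cam_t2, cs$interval)
  expect_equal(b, 0, tolerance = 1e-12)
  expect_gt(a$accuracy_deg, 19)
  # and a constant offset makes them equal (checked above); injected
  # bias + noise recovers the bias within Monte-Carlo error
  set.seed(77)
  ests <- replicate(30, {
    cs <- make_recovery_case(cam_t2, 2, 1)
    interval_bias(cs$frames, cs$track, cam_t2, cs$interval)
  })
  expect_lt(abs(mean(ests) - 2), 3 * sd(ests) / sqrt(30) + 0.01)
})

test_that("precision: constant, alternating, and Gaussian cases", {
  cs <- static_case(c(1000, 500))
  p <- interval_precision(cs$frames, cs$track, cam_t2, cs$interval)
  expect_equal(unname(p), c(0, 0))
  # alternating between A and B: RMS-S2S equals their angular distance
  A <- c(900, 540); B <- c(1020, 560)
  n <- 250
  frames <- data.frame(frame = 0:(n - 1), t = (0:(n - 1)) / 25,
                       x_px = rep(c(A[1], B[1]), length.out = n),
                       y_px = rep(c(A[2], B[2]), length.out = n),
                       missing = FALSE)
  class(frames) <- c("frame_gaze", "data.frame")
  p <- interval_precision(frames, cs$track, cam_t2, cs$interval)
  expect_equal(p[["rms_s2s_deg"]], angular_distance(A, B, cam_t2),
               tolerance = 1e-9)
  # Gaussian noise: E[step^2] = 2 * 2 * sigma^2, so RMS-S2S = 2 * sigma
  set.seed(55)
  rms <- replicate(40, {
    cs <- make_recovery_case(cam_t2, 0, 1)
    interval_precision(cs$frames, cs$track, cam_t2,
                       cs$interval)[["rms_s2s_deg"]]
  })
  se <- sd(rms) / sqrt(length(rms))
  expect_lt(abs(mean(rms) - 2), 3 * se + 0.01)
})

test_that("target speed: static, stepping, and closed-form cases", {
  n <- 100
  static <- target_track(data.frame(frame = 0:(n - 1), label = "center",
                                    x_px = 960, y_px = 540,
                                    detected = TRUE))
  iv <- data.frame(start_t = 0, end_t = 4, label = "center")
  expect_equal(target_speed(static, cam_t2, iv), 0)
  # 40 px per frame near center at 25 fps
  stepping <- target_track(data.frame(
    frame = 0:(n - 1), label = "center",
    x_px = 960 - 20 + 40 * ((0:(n - 1)) %% 2), y_px = 540,
    detected = TRUE))
  sp <- target_speed(stepping, cam_t2, iv)
  expect_equal(sp, 25 * angular_distance(c(940, 540), c(980, 540), cam_t2),
               tolerance = 1e-9)
  expect_true(is.na(target_speed(static[1, ], cam_t2, iv)))
})

test_that("gait-driven target speed matches dense numerical integration", {
  sc <- synthetic_scenario("walking", "tobii3", seed = 14)
  ses <- simulate_session(sc)
  iv <- walking_intervals(ses$track)[1, ]
  sp <- target_speed(ses$track, sc$camera, iv)
  # oracle: numerically integrate |d(angle)/dt| on a 10x denser grid
  motion <- gazeqc:::target_motion(sc, ses$schedule)
  tt <- seq(iv$start_t, iv$end_t, by = 1 / 250)
  b <- motion$bullseye(tt)
  steps <- angular_distance(cbind(b$x_px[-1], b$y_px[-1]),
                            cbind(b$x_px[-length(tt)],
                                  b$y_px[-length(tt)]), sc$camera)
  oracle <- sum(steps) / (iv$end_t - iv$start_t)
  expect_lt(abs(sp - oracle) / oracle, 0.05)
})

test_that("heatmap bins exactly and normalizes to 1000", {
  cam <- camera_model(vd_px = 1000)
  hm <- heatmap_from_points(rep(30, 5), rep(30, 5), cam)
  expect_equal(max(hm$grid), 1000)
  expect_equal(sum(hm$grid), 1000)
  hm2 <- heatmap_from_points(c(10, 10, 30, 30), c(10, 10, 10, 10), cam)
  expect_equal(sort(hm2$grid[hm2$grid > 0]), c(500, 500))
  # uniform points against a direct binning oracle
  set.seed(3)
  x <- runif(5000, 1, 1920); y <- runif(5000, 1, 1080)
  hm3 <- heatmap_from_points(x, y, cam)
  oracle <- table(factor(pmin(ceiling(y / 20), 54), levels = 1:54),
                  factor(pmin(ceiling(x / 20), 96), levels = 1:96))
  expect_equal(unclass(hm3$grid),
               matrix(as.numeric(oracle), 54, 96) * 1000 / 5000,
               ignore_attr = TRUE)
  expect_equal(sum(hm3$grid), 1000, tolerance = 1e-6)
  # out-of-bounds dropped; all-out-of-bounds errors
  expect_message(hm4 <- heatmap_from_points(c(30, -5), c(30, 10), cam),
                 "dropped")
  expect_error(heatmap_from_points(-5, 10, cam), "in-bounds")
})

test_that("median accuracy is robust to injected outliers", {
  cs <- static_case(c(1000, 540))
  frames <- cs$frames
  frames$x_px[1:10] <- 1900  # ten wild frames
  r <- interval_accuracy(frames, cs$track, cam_t2, cs$interval)
  expect_lt(r$accuracy_median_deg, r$accuracy_deg)
})

test_that("condition_summary aggregates participants, not intervals", {
  res <- data.frame(
    participant = rep(c("p1", "p2", "p3"), each = 4),
    device = "tobii2", condition = "seated_chinrest",
    label = rep(c("center", "top", "center", "left"), 3),
    accuracy_deg = c(1, 2, 3, 2, 2, 3, 4, 3, 3, 4, 5, 4))
  s <- condition_summary(res)
  per_part <- c(2, 3, 4)  # direct recomputation
  expect_equal(s$mean, mean(per_part))
  expect_equal(s$sd, sd(per_part))
  expect_equal(s$median, 3)
  expect_equal(s$n, 3)
  # central-dot filter keeps 2 intervals per participant here
  sc <- condition_summary(res, labels = "center")
  expect_equal(sc$mean, mean(c(2, 3, 4)))
  # single participant: sd flagged undefined
  s1 <- condition_summary(res[res$participant == "p1", ])
  expect_equal(s1$sd, 0)
  expect_false(s1$sd_defined)
})

test_that("frames lacking target or gaze are excluded from theta", {
  cs <- static_case(c(1000, 540))
  track <- cs$track
  track$detected[1:50] <- FALSE
  track$x_px[1:50] <- NA
  r <- interval_accuracy(cs$frames, track, cam_t2, cs$interval)
  expect_equal(r$n_frames_valid, 200)
  expect_true(r$valid)
  track$detected <- FALSE
  r2 <- interval_accuracy(cs$frames, track, cam_t2, cs$interval)
  expect_false(r2$valid)
})
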