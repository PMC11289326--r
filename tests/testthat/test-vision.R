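disk_mask <- function(h, w, cx, cy, r) {
  outer(seq_len(h), seq_len(w),
        function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

small_rgb <- function(h, w, bg = c(1, 1, 1)) {
  array(rep(bg, each = h * w), c(h, w, 3))
}

paint <- function(img, mask, col) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- col[ch]
    img[, , ch] <- plane
  }
  img
}

test_that("green_mask recovers rendered disk pixels", {
  truth <- disk_mask(120, 160, 60.3, 50.7, 12)
  img <- paint(small_rgb(120, 160), truth, c(0, 0.8, 0))
  m <- green_mask(img)
  # agreement everywhere except possibly the 1-px boundary band
  band <- disk_mask(120, 160, 60.3, 50.7, 13.5) &
    !disk_mask(120, 160, 60.3, 50.7, 10.5)
  expect_true(all(m[!band] == truth[!band]))
  # all-white frame -> empty mask; grayscale input -> format error
  expect_false(any(green_mask(small_rgb(50, 50))))
  expect_error(green_mask(array(0.5, c(50, 50, 1))), "3-channel")
  # dimming by 0.6 keeps the same component
  expect_true(all(green_mask(img * 0.6)[truth & !band]))
})

test_that("find_circles localizes disks to sub-pixel accuracy", {
  m <- disk_mask(300, 400, 150.4, 120.6, 20) |
    disk_mask(300, 400, 310.2, 200.8, 20)
  circ <- find_circles(m, c(14, 26))
  expect_equal(nrow(circ), 2)
  circ <- circ[order(circ$x_px), ]
  expect_lt(abs(circ$x_px[1] - 150.4), 1)
  expect_lt(abs(circ$y_px[1] - 120.6), 1)
  expect_lt(abs(circ$x_px[2] - 310.2), 1)
  expect_lt(abs(circ$radius_px[1] - 20), 1.5)
  # returned centers are mutually separated
  expect_true(all(dist(circ[, c("x_px", "y_px")]) >= 14))
  # blank mask -> empty result, not an error
  expect_equal(nrow(find_circles(matrix(FALSE, 100, 100), c(5, 20))), 0)
})

test_that("find_circles is robust to salt noise", {
  set.seed(31)
  centers <- cbind(x = c(80, 200, 320), y = c(90, 220, 100))
  m <- disk_mask(300, 400, 80, 90, 15) |
    disk_mask(300, 400, 200, 220, 15) | disk_mask(300, 400, 320, 100, 15)
  noisy <- m
  noisy[sample(length(m), 200)] <- TRUE
  circ <- find_circles(noisy, c(10, 20), n_best = 3)
  expect_equal(nrow(circ), 3)
  for (i in 1:3) {
    d <- sqrt((circ$x_px - centers[i, "x"])^2 +
                (circ$y_px - centers[i, "y"])^2)
    expect_lt(min(d), 2)
  }
})

test_that("label_dots assigns the compass labels invariantly", {
  ring <- function(cx, cy, r, roll = 0) {
    ang <- (0:7) * 45 * pi / 180 + roll * pi / 180
    data.frame(x_px = c(cx, cx + r * cos(ang)),
               y_px = c(cy, cy - r * sin(ang)))
  }
  base <- ring(960, 540, 300)
  lab <- label_dots(base)
  expect_equal(lab$label, dot_labels())
  # translation + scale leave labels unchanged
  moved <- ring(960 + 300, 540 - 200, 240)
  expect_equal(label_dots(moved)$label, dot_labels())
  # roll within +/- 15 degrees
  expect_equal(label_dots(ring(960, 540, 300, roll = 14))$label,
               dot_labels())
  expect_equal(label_dots(ring(960, 540, 300, roll = -14))$label,
               dot_labels())
  # top dot absent: 8 labels, no "top"
  lab8 <- label_dots(base[-4, ])  # row 4 is the "top" dot
  expect_equal(nrow(lab8), 8)
  expect_false("top" %in% lab8$label)
  # fewer than 5 candidates: frame-level failure
  expect_null(label_dots(base[1:4, ]))
})

test_that("carpet_vanishing_point solves the analytic 2x2 system", {
  # region between y = 0.30x + 100 and y = -0.28x + 650, drawn as carpet
  h <- 1080; w <- 1920
  xi <- 550 / 0.58; yi <- 0.30 * xi + 100  # analytic intersection
  img <- small_rgb(h, w, c(0.9, 0.9, 0.9))
  for (y in ceiling(yi + 8):h) {
    xl <- max(1, ceiling((650 - y) / 0.28))
    xr <- min(w, floor((y - 100) / 0.30))
    if (xl <= xr) for (ch in 1:3)
      img[y, xl:xr, ch] <- c(0.8, 0.12, 0.12)[ch]
  }
  vp <- carpet_vanishing_point(img)
  expect_lt(abs(vp$x_px - xi), 2)
  expect_lt(abs(vp$y_px - yi), 2)

  # 1-px jitter on the edges still lands within 5 px
  set.seed(8)
  imgj <- small_rgb(h, w, c(0.9, 0.9, 0.9))
  for (y in ceiling(yi + 8):h) {
    xl <- max(1, ceiling((650 - y) / 0.28 + sample(-1:1, 1)))
    xr <- min(w, floor((y - 100) / 0.30 + sample(-1:1, 1)))
    if (xl <= xr) for (ch in 1:3)
      imgj[y, xl:xr, ch] <- c(0.8, 0.12, 0.12)[ch]
  }
  vpj <- carpet_vanishing_point(imgj)
  expect_lt(sqrt((vpj$x_px - xi)^2 + (vpj$y_px - yi)^2), 5)

  # parallel edges -> no-intersection error; no red -> detection failure
  imgp <- small_rgb(400, 400, c(0.9, 0.9, 0.9))
  imgp[100:400, 150:250, 1] <- 0.8
  imgp[100:400, 150:250, 2] <- 0.12
  imgp[100:400, 150:250, 3] <- 0.12
  expect_error(carpet_vanishing_point(imgp), "parallel")
  expect_error(carpet_vanishing_point(small_rgb(400, 400)), "not found")
})

test_that("locate_bullseye flags undetected frames instead of failing", {
  img <- small_rgb(400, 400, c(0.88, 0.88, 0.88))
  obs <- locate_bullseye(img, c(200, 200), radius_range = c(5, 40))
  expect_false(obs$detected)
  expect_true(is.na(obs$x_px))
})

test_that("smooth_track removes spikes and respects slow motion", {
  mk <- function(x, y, det = TRUE) target_track(data.frame(
    frame = seq_along(x) - 1, label = "bullseye", x_px = x, y_px = y,
    detected = det))
  # constant track unchanged
  tr <- mk(rep(100, 20), rep(50, 20))
  expect_equal(smooth_track(tr)$x_px, rep(100, 20))
  # one-frame 50-px spike removed
  x <- rep(100, 21); x[11] <- 150
  sm <- smooth_track(mk(x, rep(0.5 * x, 1)))
  expect_equal(sm$x_px, rep(100, 21))
  # slow sinusoid (period >> window) barely altered away from the ends,
  # where the centered window is truncated
  t <- 0:199
  x <- 500 + 100 * sin(2 * pi * t / 100)
  sm <- smooth_track(mk(x, x))
  expect_lt(max(abs(sm$x_px - x)[3:198]), 1)
  # equivariance to axis swap and translation
  y2 <- rep(100, 21); y2[11] <- 150
  a <- smooth_track(mk(y2 + 7, rep(1, 21)))
  b <- smooth_track(mk(rep(1, 21), y2 + 7))
  expect_equal(a$x_px - 7, b$y_px - 7)
  # undetected frames are ignored, not interpolated
  det <- rep(TRUE, 21); det[11] <- FALSE
  sm <- smooth_track(mk(x[1:21], x[1:21], det))
  expect_false(sm$detected[11])
})

test_that("detect_dots finds and labels a rendered pose", {
  cam <- camera_model(vd_px = 1132.4)
  pose <- render_pose(cam, tx = 120, ty = -60, scale = 0.9, roll_deg = 8)
  det <- detect_dots(pose$frame, radius_range = c(6, 16))
  expect_true(all(det$detected))
  m <- merge(det, pose$state, by = "label")
  err <- sqrt((m$x_px.x - m$x_px.y)^2 + (m$y_px.x - m$y_px.y)^2)
  expect_lt(mean(err), 1)
})
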