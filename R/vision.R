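#' Target track container
#'
#' Per-frame localized positions of the gaze targets in scene-camera
#' pixels, one row per (frame, label). `detected = FALSE` rows keep their
#' place so downstream interval logic can distinguish "target out of view"
#' (not an eye-tracking failure) from missing gaze.
#'
#' @param df Data frame with columns `frame`, `label`, `x_px`, `y_px`,
#'   `detected`, and optionally `radius_px` and `visible` (carpet/target
#'   visibility used by walking-interval extraction).
#' @return A data frame of class `target_track`.
#' @export
target_track <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("frame", "label", "x_px", "y_px", "detected") %in%
                  names(df)))
  if (anyDuplicated(df[c("frame", "label")]))
    stop("at most one observation per (label, frame)", call. = FALSE)
  if ("radius_px" %in% names(df) &&
      any(df$radius_px <= 0 & df$detected, na.rm = TRUE))
    stop("radius_px must be positive where present", call. = FALSE)
  df <- df[order(df$label, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("target_track", "data.frame")
  df
}

color_mask <- function(frame, hue, sat_min, val_min) {
  if (length(dim(frame)) != 3 || dim(frame)[3] < 3)
    stop("color masking needs a 3-channel frame", call. = FALSE)
  d <- dim(frame)
  r <- as.vector(frame[, , 1]); g <- as.vector(frame[, , 2])
  b <- as.vector(frame[, , 3])
  v <- pmax(r, g, b)
  c_ <- v - pmin(r, g, b)
  # saturation/value gates first: hue is only computed for the (few)
  # saturated pixels, which keeps full-HD masking cheap
  sel <- which(v >= val_min & c_ >= sat_min * v & v > 0)
  out <- logical(length(v))
  if (length(sel)) {
    rs <- r[sel]; gs <- g[sel]; bs <- b[sel]; cs <- c_[sel]
    h <- numeric(length(sel))
    i1 <- rs >= gs & rs >= bs
    i2 <- !i1 & gs >= bs
    i3 <- !i1 & !i2
    h[i1] <- ((gs[i1] - bs[i1]) / cs[i1]) %% 6
    h[i2] <- (bs[i2] - rs[i2]) / cs[i2] + 2
    h[i3] <- (rs[i3] - gs[i3]) / cs[i3] + 4
    h <- h * 60
    in_hue <- if (hue[1] <= hue[2]) h >= hue[1] & h <= hue[2]
              else h >= hue[1] | h <= hue[2]
    out[sel[in_hue]] <- TRUE
  }
  matrix(out, d[1], d[2])
}

#' Color-band masks for the gaze targets
#'
#' `green_mask()` selects pixels whose HSV color falls inside a green band
#' (the printed dots and bullseye rings); `red_mask()` selects the red
#' carpet. Threshold defaults are tuned on the bundled renderer and are
#' plain parameters — real recordings will need their own band.
#'
#' @param frame `[h, w, 3]` numeric array in `[0, 1]`.
#' @param hue Hue interval in degrees (for red the interval may wrap,
#'   e.g. `c(340, 20)`).
#' @param sat_min,val_min Minimum saturation / value.
#' @return Logical matrix `[h, w]`.
#' @export
green_mask <- function(frame, hue = c(80, 160), sat_min = 0.35,
                       val_min = 0.2) {
  color_mask(frame, hue, sat_min, val_min)
}

#' @rdname green_mask
#' @export
red_mask <- function(frame, hue = c(340, 20), sat_min = 0.35,
                     val_min = 0.2) {
  color_mask(frame, hue, sat_min, val_min)
}

mask_edges <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  interior <- matrix(FALSE, h, w)
  if (h > 2 && w > 2)
    interior[2:(h - 1), 2:(w - 1)] <-
      mask[1:(h - 2), 2:(w - 1)] & mask[3:h, 2:(w - 1)] &
      mask[2:(h - 1), 1:(w - 2)] & mask[2:(h - 1), 3:w]
  which(mask & !interior, arr.ind = TRUE)  # rows: (y, x)
}

#' Circular Hough transform
#'
#' Detects circles in a binary mask (or a frame, which is first passed
#' through [green_mask()]). Edge pixels of the mask vote for candidate
#' centers along circles of each radius in `radius_range`; accumulator
#' peaks are extracted greedily with a minimum mutual center distance and
#' refined to sub-pixel precision by an algebraic (Kasa) circle fit to the
#' supporting edge pixels.
#'
#' @param x Logical matrix mask, or `[h, w, 3]` frame.
#' @param radius_range `c(min, max)` candidate radii in pixels.
#' @param n_best Maximum number of circles returned.
#' @param score_min Minimum Hough score in `[0, 1]` (fraction of the
#'   sampled directions supported by edge votes).
#' @param min_dist Minimum distance between returned centers; defaults to
#'   `max(radius_range[1], 5)`.
#' @param n_theta Angular samples per edge pixel.
#' @return Data frame with columns `x_px`, `y_px`, `radius_px`, `score`,
#'   sorted by decreasing score. Empty input yields zero rows (not an
#'   error).
#' @export
find_circles <- function(x, radius_range, n_best = 16, score_min = 0.25,
                         min_dist = NULL, n_theta = 60) {
  mask <- if (is.matrix(x)) x else green_mask(x)
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  stopifnot(length(radius_range) == 2, radius_range[1] > 0,
            radius_range[2] < min(w, h) / 2,
            radius_range[1] <= radius_range[2])
  if (is.null(min_dist)) min_dist <- max(radius_range[1], 5)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      radius_px = numeric(0), score = numeric(0))
  edges <- mask_edges(mask)
  if (nrow(edges) == 0) return(empty)
  ey <- edges[, 1]; ex <- edges[, 2]
  # accumulate only inside the edge bounding box (+ max radius margin)
  rmax <- ceiling(radius_range[2])
  bx0 <- max(1L, min(ex) - rmax); bx1 <- min(w, max(ex) + rmax)
  by0 <- max(1L, min(ey) - rmax); by1 <- min(h, max(ey) + rmax)
  bw <- bx1 - bx0 + 1L; bh <- by1 - by0 + 1L
  # radius step 2 px keeps every true radius within the ~1-px vote smear
  radii <- unique(round(seq(radius_range[1], radius_range[2],
                            by = if (diff(radius_range) > 78)
                              diff(radius_range) / 39 else 2)))
  if (radii[length(radii)] < radius_range[2])
    radii <- c(radii, round(radius_range[2]))
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
  cand <- list()
  for (r in radii) {
    cx <- round(outer(ex, r * cos(theta), `+`)) - bx0 + 1L
    cy <- round(outer(ey, r * sin(theta), `+`)) - by0 + 1L
    keep <- cx >= 1 & cx <= bw & cy >= 1 & cy <= bh
    idx <- (cx[keep] - 1L) * bh + cy[keep]
    votes <- tabulate(idx, nbins = bh * bw)
    hits <- which(votes >= score_min * n_theta)
    if (length(hits))
      cand[[length(cand) + 1]] <- data.frame(
        x_px = ((hits - 1L) %/% bh) + bx0,
        y_px = ((hits - 1L) %% bh) + by0,
        radius_px = r,
        score = votes[hits] / n_theta)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score), , drop = FALSE]
  picked <- empty
  for (i in seq_len(nrow(cand))) {
    if (nrow(picked) >= n_best) break
    if (nrow(picked) == 0 ||
        all((picked$x_px - cand$x_px[i])^2 +
            (picked$y_px - cand$y_px[i])^2 >= min_dist^2))
      picked <- rbind(picked, cand[i, ])
  }
  # sub-pixel refinement on the supporting edge pixels
  for (i in seq_len(nrow(picked))) {
    d <- sqrt((ex - picked$x_px[i])^2 + (ey - picked$y_px[i])^2)
    sel <- abs(d - picked$radius_px[i]) <= 2
    if (sum(sel) >= 6) {
      fit <- kasa_circle(ex[sel], ey[sel])
      if (!is.null(fit) &&
          (fit$x - picked$x_px[i])^2 + (fit$y - picked$y_px[i])^2 <= 9) {
        picked$x_px[i] <- fit$x
        picked$y_px[i] <- fit$y
        picked$radius_px[i] <- fit$r
      }
    }
  }
  rownames(picked) <- NULL
  picked
}

# Algebraic least-squares circle fit (Kasa): x^2+y^2 = 2ax + 2by + c
kasa_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  z <- x^2 + y^2
  fit <- tryCatch(qr.solve(A, z), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  r2 <- fit[3] + fit[1]^2 + fit[2]^2
  if (r2 <= 0) return(NULL)
  list(x = fit[1], y = fit[2], r = sqrt(r2))
}

#' Label detected dot centers
#'
#' Assigns the nine protocol labels to detected circle centers: the
#' center dot is the candidate minimizing the summed distance to all
#' others, and the remaining dots are labelled by their angle about it
#' (eight 45-degree compass sectors, with "top" meaning smaller y). The
#' mapping is invariant to global translation and scaling, and to roll up
#' to +/- 15 degrees (within-sector rotation). Two candidates falling in
#' one sector are disambiguated by closeness to the median ring radius.
#'
#' @param centers Data frame with columns `x_px`, `y_px` (>= 5 rows), as
#'   returned by [find_circles()].
#' @return Data frame with columns `label`, `x_px`, `y_px` (one row per
#'   assigned label; absent dots are simply not listed), or `NULL` when
#'   fewer than 5 candidates are supplied (frame-level detection failure).
#' @export
label_dots <- function(centers) {
  if (is.null(centers) || nrow(centers) < 5) return(NULL)
  x <- centers$x_px; y <- centers$y_px
  dmat <- as.matrix(stats::dist(cbind(x, y)))
  ci <- which.min(rowSums(dmat))
  cx <- x[ci]; cy <- y[ci]
  out <- data.frame(label = "center", x_px = cx, y_px = cy,
                    stringsAsFactors = FALSE)
  rest <- setdiff(seq_along(x), ci)
  if (!length(rest)) return(out)
  ang <- atan2(-(y[rest] - cy), x[rest] - cx) * 180 / pi  # y-down image coords
  sector <- (round(ang / 45) %% 8) + 1  # 1=right, 2=top-right, ... ccw
  ring <- sqrt((x[rest] - cx)^2 + (y[rest] - cy)^2)
  ring_med <- stats::median(ring)
  labels8 <- dot_labels()[-1]
  for (s in unique(sector)) {
    in_s <- rest[sector == s]
    if (length(in_s) > 1) {
      dev <- abs(sqrt((x[in_s] - cx)^2 + (y[in_s] - cy)^2) - ring_med)
      in_s <- in_s[which.min(dev)]
    }
    out <- rbind(out, data.frame(label = labels8[s], x_px = x[in_s],
                                 y_px = y[in_s], stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

fit_edge_line <- function(xs, ys) {
  # x = a + b*y least squares with one outlier-trimming pass
  fit <- stats::lm.fit(cbind(1, ys), xs)
  res <- fit$residuals
  keep <- abs(res) <= 3 * max(stats::mad(res), 0.5)
  if (sum(keep) >= 5 && any(!keep))
    fit <- stats::lm.fit(cbind(1, ys[keep]), xs[keep])
  c(a = unname(fit$coefficients[1]), b = unname(fit$coefficients[2]))
}

#' Vanishing point of the carpet edges
#'
#' Fits a straight line to each long edge of the red carpet region (left
#' and right extreme columns of the red mask, per image row) and returns
#' the intersection of the two lines: the approximate image position of
#' the walking target, used as a search prior for bullseye detection.
#'
#' @param frame `[h, w, 3]` array, or a logical matrix already masking the
#'   carpet.
#' @param min_rows Minimum number of mask rows required for a fit.
#' @param ... Passed to [red_mask()] when `frame` is an image.
#' @return List with elements `x_px`, `y_px` and `lines` (the two fitted
#'   `x = a + b*y` coefficient pairs).
#' @export
carpet_vanishing_point <- function(frame, min_rows = 20, ...) {
  mask <- if (is.matrix(frame)) frame else red_mask(frame, ...)
  rows <- which(rowSums(mask) >= 2)
  if (length(rows) < min_rows)
    stop("carpet region not found in frame", call. = FALSE)
  left <- apply(mask[rows, , drop = FALSE], 1, function(r) which(r)[1])
  right <- apply(mask[rows, , drop = FALSE], 1, function(r) max(which(r)))
  # rows where the carpet runs off the image show the border, not the
  # carpet edge; they must not enter the line fits
  l_ok <- left > 1
  r_ok <- right < ncol(mask)
  if (sum(l_ok) < min_rows || sum(r_ok) < min_rows)
    stop("carpet region not found in frame", call. = FALSE)
  l1 <- fit_edge_line(left[l_ok], rows[l_ok])
  l2 <- fit_edge_line(right[r_ok], rows[r_ok])
  ang <- abs(atan(l1["b"]) - atan(l2["b"])) * 180 / pi
  if (ang < 0.5)
    stop("carpet edges are parallel; no vanishing point", call. = FALSE)
  yv <- (l2["a"] - l1["a"]) / (l1["b"] - l2["b"])
  xv <- l1["a"] + l1["b"] * yv
  list(x_px = unname(xv), y_px = unname(yv),
       lines = list(left = l1, right = l2))
}

#' Locate the bullseye around a positional prior
#'
#' Crops a window around the prior (from [carpet_vanishing_point()] or the
#' previous frame's detection), masks the green rings and runs
#' [find_circles()] inside it. Returns an undetected observation rather
#' than failing when nothing is found.
#'
#' @param frame `[h, w, 3]` array.
#' @param prior List or vector with the prior center (`x_px`, `y_px`).
#' @param radius_range Candidate ring radii in pixels.
#' @param window_px Half-size of the square search window; defaults to
#'   `3 * radius_range[2]`.
#' @param frame_index Frame index recorded in the observation.
#' @param ... Passed to [green_mask()].
#' @return One-row data frame with columns `frame`, `label`, `x_px`,
#'   `y_px`, `radius_px`, `detected`.
#' @export
locate_bullseye <- function(frame, prior, radius_range = c(6, 80),
                            window_px = NULL, frame_index = 0L, ...) {
  px <- if (is.list(prior)) prior$x_px else prior[1]
  py <- if (is.list(prior)) prior$y_px else prior[2]
  if (is.null(window_px)) window_px <- 3 * radius_range[2]
  h <- dim(frame)[1]; w <- dim(frame)[2]
  x0 <- max(1, floor(px - window_px)); x1 <- min(w, ceiling(px + window_px))
  y0 <- max(1, floor(py - window_px)); y1 <- min(h, ceiling(py + window_px))
  undetected <- data.frame(frame = frame_index, label = "bullseye",
                           x_px = NA_real_, y_px = NA_real_,
                           radius_px = NA_real_, detected = FALSE)
  if (x1 - x0 < 2 * radius_range[1] || y1 - y0 < 2 * radius_range[1])
    return(undetected)
  crop <- frame[y0:y1, x0:x1, , drop = FALSE]
  rmax_allowed <- min(x1 - x0 + 1, y1 - y0 + 1) / 2 - 1
  rr <- c(radius_range[1], min(radius_range[2], rmax_allowed))
  if (rr[1] > rr[2]) return(undetected)
  gm <- green_mask(crop, ...)
  circ <- find_circles(gm, rr, n_best = 3)
  if (nrow(circ) == 0) return(undetected)
  # the concentric rings are point-symmetric about the bullseye center,
  # so the centroid of the masked pixels around the Hough candidate
  # refines the center far better than any single ring's circle fit
  px_idx <- which(gm, arr.ind = TRUE)
  d2 <- (px_idx[, 2] - circ$x_px[1])^2 + (px_idx[, 1] - circ$y_px[1])^2
  near <- d2 <= (1.3 * circ$radius_px[1] + 3)^2
  if (!any(near)) return(undetected)
  data.frame(frame = frame_index, label = "bullseye",
             x_px = mean(px_idx[near, 2]) + x0 - 1,
             y_px = mean(px_idx[near, 1]) + y0 - 1,
             radius_px = sqrt(max(d2[near])), detected = TRUE)
}

#' Detect the nine-dot grid in one frame
#'
#' Convenience wrapper: [green_mask()] then [find_circles()] then
#' [label_dots()], returning target-track rows for one frame. Frames in
#' which fewer than five dots are found yield all-undetected rows.
#'
#' @param frame `[h, w, 3]` array.
#' @param radius_range Candidate dot radii in pixels.
#' @param frame_index Frame index recorded in the observations.
#' @param ... Passed to [green_mask()].
#' @return Data frame with one row per protocol dot label.
#' @export
detect_dots <- function(frame, radius_range = c(5, 20), frame_index = 0L,
                        ...) {
  circ <- find_circles(green_mask(frame, ...), radius_range, n_best = 12)
  # partially out-of-frame slivers and noise blobs score well below the
  # full disks; keep only candidates in the top half of the score range
  if (nrow(circ) > 0)
    circ <- circ[circ$score >= 0.5 * max(circ$score), , drop = FALSE]
  lab <- label_dots(circ)
  out <- data.frame(frame = frame_index, label = dot_labels(),
                    x_px = NA_real_, y_px = NA_real_, detected = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(lab)) {
    m <- match(out$label, lab$label)
    hit <- !is.na(m)
    out$x_px[hit] <- lab$x_px[m[hit]]
    out$y_px[hit] <- lab$y_px[m[hit]]
    out$detected[hit] <- TRUE
  }
  out
}

#' Smooth a target track
#'
#' Per-label, per-axis centered moving median over a window of video
#' frames (default 5 frames = 0.20 s at 25 fps), omitting undetected
#' frames, to remove single-frame detection jitter. Undetected frames stay
#' undetected; detected coordinates are replaced by the window median.
#'
#' @param track A [target_track()].
#' @param window_frames Odd window length in frames.
#' @return The smoothed [target_track()].
#' @export
smooth_track <- function(track, window_frames = 5) {
  stopifnot(inherits(track, "target_track"), window_frames %% 2 == 1)
  hw <- (window_frames - 1) / 2
  out <- track
  for (lb in unique(track$label)) {
    sel <- which(track$label == lb)
    sub <- track[sel, ]
    xs <- ifelse(sub$detected, sub$x_px, NA_real_)
    ys <- ifelse(sub$detected, sub$y_px, NA_real_)
    sx <- roll_median_na(xs, hw, hw)
    sy <- roll_median_na(ys, hw, hw)
    keep <- sub$detected
    out$x_px[sel[keep]] <- sx[keep]
    out$y_px[sel[keep]] <- sy[keep]
  }
  out
}
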