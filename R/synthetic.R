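#' Synthetic-session scenario
#'
#' The stated world for a simulated eye-tracking session, with ground
#' truth for every pipeline stage. Conditions mirror the evaluation
#' protocol: `seated_chinrest` (static nine-dot wall pattern, eyes only),
#' `seated_free` (the wearer also turns their head, re-centering the
#' instructed dot in the scene image), and `walking` (approach toward a
#' bullseye whose image position oscillates with the wearer's gait).
#'
#' Geometry defaults reproduce the physical setup: a 536-mm-diameter ring
#' of 20-mm dots viewed from 1 m (15 degrees eccentricity, 1.1-degree dot
#' span), a 480-mm bullseye, and the two device profiles including the
#' scene-camera pitch that shifts targets vertically in the image.
#'
#' @param condition One of `"seated_chinrest"`, `"seated_free"`,
#'   `"walking"`.
#' @param device `"tobii2"` (50 Hz) or `"tobii3"` (100 Hz).
#' @param bias_deg,bias_dir_deg Magnitude (degrees) and image-plane
#'   direction of the systematic gaze offset (0 = rightward, 90 =
#'   downward).
#' @param noise_sd_deg SD of the isotropic Gaussian gaze noise per axis,
#'   in degrees.
#' @param blink_rate_hz Poisson rate of blink events.
#' @param blink_median_s,blink_sdlog Lognormal blink-duration parameters
#'   (median in seconds, log-scale SD).
#' @param head_recenter Fraction of the instructed dot's eccentricity
#'   absorbed by head rotation in the free-head condition, in `[0, 1]`.
#' @param gait_amp_px Named vector `c(x=, y=)`: image-plane gait
#'   oscillation amplitudes for walking.
#' @param step_frequency_hz Step frequency; vertical bounce at this
#'   frequency, lateral sway at half of it.
#' @param approach_radius_px `c(start, end)` apparent bullseye radius over
#'   a walk.
#' @param walk_duration_s,turnaround_s Duration of each walk epoch and of
#'   the carpet-invisible turnaround between the two walks.
#' @param tremor_px Amplitude of the slow head-tremor wander of the whole
#'   target layout in the seated conditions.
#' @param spacing_s Seconds between audio instructions (seated).
#' @param seed Integer seed; fixes every random draw of the session.
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(condition = c("seated_chinrest",
                                             "seated_free", "walking"),
                               device = c("tobii2", "tobii3"),
                               bias_deg = 1, bias_dir_deg = 45,
                               noise_sd_deg = 0.5,
                               blink_rate_hz = 0.25,
                               blink_median_s = 0.15, blink_sdlog = 0.4,
                               head_recenter = 0.8,
                               gait_amp_px = c(x = 25, y = 18),
                               step_frequency_hz = 1.8,
                               approach_radius_px = c(8, 60),
                               walk_duration_s = 20, turnaround_s = 5,
                               tremor_px = 3,
                               spacing_s = 12,
                               seed = 1L) {
  condition <- match.arg(condition)
  device <- match.arg(device)
  stopifnot(bias_deg >= 0, noise_sd_deg >= 0, blink_rate_hz >= 0,
            blink_median_s > 0, head_recenter >= 0, head_recenter <= 1,
            all(gait_amp_px >= 0), step_frequency_hz > 0,
            all(approach_radius_px > 0), walk_duration_s > 10,
            tremor_px >= 0, spacing_s > 0)
  prof <- device_profile(device)
  structure(list(
    condition = condition, device = device, rate_hz = prof$rate_hz,
    camera = prof$camera,
    bias_deg = bias_deg, bias_dir_deg = bias_dir_deg,
    noise_sd_deg = noise_sd_deg,
    blink_rate_hz = blink_rate_hz, blink_median_s = blink_median_s,
    blink_sdlog = blink_sdlog,
    head_recenter = head_recenter,
    gait_amp_px = gait_amp_px, step_frequency_hz = step_frequency_hz,
    approach_radius_px = approach_radius_px,
    walk_duration_s = walk_duration_s, turnaround_s = turnaround_s,
    tremor_px = tremor_px, spacing_s = spacing_s,
    wall_distance_mm = 1000, ring_radius_mm = 268, dot_radius_mm = 10,
    seed = as.integer(seed)), class = "synthetic_scenario")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate an instruction schedule for a condition
#'
#' Seated protocols produce 19 instructions at the configured spacing:
#' the central dot at the first, middle (10th) and last position and the
#' eight peripheral dots twice each, shuffled into the remaining slots.
#' Walking protocols produce one `"bullseye"` entry per walk epoch.
#'
#' @param condition Condition name, see [synthetic_scenario()].
#' @param seed Integer seed controlling the shuffle.
#' @param spacing_s Seconds between instructions (seated).
#' @param walk_duration_s,turnaround_s Walking epoch timing.
#' @return An [instruction_schedule()].
#' @export
make_protocol <- function(condition, seed = 1L, spacing_s = 12,
                          walk_duration_s = 20, turnaround_s = 5) {
  if (condition == "walking") {
    return(instruction_schedule(
      onset_s = c(0, walk_duration_s + turnaround_s),
      label = c("bullseye", "bullseye")))
  }
  labels <- rep(NA_character_, 19)
  labels[c(1, 10, 19)] <- "center"
  periph <- rep(dot_labels()[-1], each = 2)
  labels[is.na(labels)] <- with_seed(seed, sample(periph))
  instruction_schedule(onset_s = (0:18) * spacing_s, label = labels)
}

# Static image-pixel layout of the nine dots for a scenario (no tremor)
dot_layout <- function(scenario) {
  cam <- scenario$camera
  cx <- cam$width_px / 2; cy <- cam$height_px / 2
  ring_px <- deg_to_px(
    atan(scenario$ring_radius_mm / scenario$wall_distance_mm) * 180 / pi,
    cam)
  dot_px <- deg_to_px(
    atan(scenario$dot_radius_mm / scenario$wall_distance_mm) * 180 / pi,
    cam)
  pitch_dy <- -deg_to_px(cam$pitch_deg, cam)
  ang <- (0:7) * 45 * pi / 180  # right, top-right, ... counter-clockwise
  data.frame(label = dot_labels(),
             x_px = cx + c(0, cos(ang) * ring_px),
             y_px = cy + pitch_dy + c(0, -sin(ang) * ring_px),
             radius_px = dot_px,
             stringsAsFactors = FALSE)
}

# Continuous target motion model, vectorized over time.
#
# Returns a list of closures:
#   layout_offset(t) -> n x 2 matrix: translation of the whole target
#     layout (head turn + tremor) at each time (seated conditions)
#   bullseye(t) -> data.frame x_px, y_px, radius_px, visible (walking)
#   state(t) -> per-target data.frame at one scalar time (for rendering)
target_motion <- function(scenario, schedule) {
  cam <- scenario$camera
  cx <- cam$width_px / 2; cy <- cam$height_px / 2
  phases <- with_seed(scenario$seed + 101L, stats::runif(4, 0, 2 * pi))
  tremor <- function(t) {
    a <- scenario$tremor_px
    cbind(a * sin(2 * pi * 0.25 * t + phases[1]),
          a * sin(2 * pi * 0.21 * t + phases[2]))
  }
  if (scenario$condition == "walking") {
    amp <- scenario$gait_amp_px
    f <- scenario$step_frequency_hz
    r0 <- scenario$approach_radius_px[1]
    r1 <- scenario$approach_radius_px[2]
    Tw <- scenario$walk_duration_s
    pitch_dy <- -deg_to_px(cam$pitch_deg, cam)
    starts <- schedule$onset_s
    bullseye <- function(t) {
      k <- findInterval(t, starts)
      tt <- t - starts[pmax(k, 1)]
      visible <- k >= 1 & tt <= Tw
      tt <- pmin(pmax(tt, 0), Tw)
      data.frame(
        x_px = cx + amp[["x"]] * sin(pi * f * t + phases[3]),
        y_px = cy + pitch_dy + amp[["y"]] * sin(2 * pi * f * t + phases[4]),
        radius_px = r0 * r1 / (r1 - (r1 - r0) * tt / Tw),
        visible = visible)
    }
    list(bullseye = bullseye,
         state = function(t) {
           b <- bullseye(t)
           cbind(data.frame(label = "bullseye", stringsAsFactors = FALSE), b)
         })
  } else {
    layout <- dot_layout(scenario)
    recenter <- scenario$head_recenter *
      (scenario$condition == "seated_free")
    onsets <- schedule$onset_s
    # head-turn translation goal per instruction; raised-cosine ramp
    ramp_delay <- 0.3; ramp_dur <- 1.0
    li <- match(schedule$label, layout$label)
    goals <- rbind(c(0, 0),
                   -recenter * cbind(layout$x_px[li] - cx,
                                     layout$y_px[li] - cy))
    layout_offset <- function(t) {
      k <- findInterval(t, onsets)
      off <- goals[k + 1, , drop = FALSE]
      if (recenter > 0) {
        u <- (t - onsets[pmax(k, 1)] - ramp_delay) / ramp_dur
        w <- ifelse(k < 1, 1, pmin(pmax((1 - cos(pi * pmin(u, 1))) / 2,
                                        0), 1))
        w[u <= 0] <- 0
        w[k < 1] <- 1  # before the first onset there is nothing to ramp
        prev <- goals[pmax(k, 1), , drop = FALSE]
        off <- prev * (1 - w) + off * w
      }
      off + tremor(t)
    }
    list(layout = layout, layout_offset = layout_offset,
         state = function(t) {
           off <- layout_offset(t)
           data.frame(label = layout$label,
                      x_px = layout$x_px + off[1, 1],
                      y_px = layout$y_px + off[1, 2],
                      radius_px = layout$radius_px, visible = TRUE,
                      stringsAsFactors = FALSE)
         })
  }
}

session_span <- function(scenario, schedule) {
  if (scenario$condition == "walking")
    max(schedule$onset_s) + scenario$walk_duration_s +
      scenario$turnaround_s
  else max(schedule$onset_s) + scenario$spacing_s
}

#' Simulate the per-frame target track of a session
#'
#' Samples the continuous target motion model at every video frame:
#' static dots plus slow head tremor (chinrest), a layout that translates
#' so the instructed dot approaches the image center after each
#' instruction (free head), or a bullseye oscillating with the gait while
#' its apparent radius grows along the approach (walking). The camera
#' pitch shifts all targets vertically. Targets outside the image bounds
#' are marked undetected; walking rows carry the carpet-visibility flag.
#'
#' @param scenario A [synthetic_scenario()].
#' @param schedule An [instruction_schedule()], typically from
#'   [make_protocol()].
#' @return A [target_track()] with a `visible` column.
#' @export
simulate_target_track <- function(scenario, schedule) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (scenario$condition == "walking" &&
      !all(schedule$label == "bullseye"))
    stop("walking scenario requires a bullseye schedule", call. = FALSE)
  if (scenario$condition != "walking" &&
      any(schedule$label == "bullseye"))
    stop("seated scenario cannot use a bullseye schedule", call. = FALSE)
  cam <- scenario$camera
  motion <- target_motion(scenario, schedule)
  n_frames <- ceiling(session_span(scenario, schedule) *
                        cam$frame_rate_hz)
  tf <- (seq_len(n_frames) - 1L) / cam$frame_rate_hz
  if (scenario$condition == "walking") {
    b <- motion$bullseye(tf)
    df <- cbind(data.frame(frame = seq_len(n_frames) - 1L,
                           label = "bullseye", stringsAsFactors = FALSE), b)
  } else {
    off <- motion$layout_offset(tf)
    layout <- motion$layout
    df <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
      data.frame(frame = seq_len(n_frames) - 1L, label = layout$label[i],
                 x_px = layout$x_px[i] + off[, 1],
                 y_px = layout$y_px[i] + off[, 2],
                 radius_px = layout$radius_px[i], visible = TRUE,
                 stringsAsFactors = FALSE)
    }))
  }
  df$detected <- df$x_px >= 1 & df$x_px <= cam$width_px &
    df$y_px >= 1 & df$y_px <= cam$height_px &
    (df$visible | scenario$condition != "walking")
  df$x_px[!df$detected] <- NA_real_
  df$y_px[!df$detected] <- NA_real_
  df$radius_px[!df$detected] <- NA_real_
  target_track(df[, c("frame", "label", "x_px", "y_px", "radius_px",
                      "detected", "visible")])
}

#' Simulate a gaze recording with known ground truth
#'
#' Gaze samples follow the instructed target with a uniform 0.3-0.5-s
#' reaction lag and an instantaneous (saccadic) jump, offset by the
#' scenario's constant bias vector and isotropic Gaussian noise (both
#' specified in degrees and converted to pixels through the camera
#' model). Blinks arrive as a Poisson process with lognormal durations and
#' replace the affected samples with invalid ones. The returned truth log
#' records every injected quantity.
#'
#' @param scenario A [synthetic_scenario()].
#' @param track Unused directly (gaze is driven by the same continuous
#'   motion model that generated the track); accepted for interface
#'   symmetry and validated against the scenario when supplied.
#' @param schedule An [instruction_schedule()].
#' @return List with elements `recording` (a [gaze_recording()]) and
#'   `truth` (list: `bias_deg`, `bias_px`, `noise_sd_px`, `lags`,
#'   `blinks`, `blink_time_s`, `span_s`).
#' @export
simulate_gaze <- function(scenario, track = NULL, schedule) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  cam <- scenario$camera
  rate <- scenario$rate_hz
  span <- session_span(scenario, schedule)
  motion <- target_motion(scenario, schedule)
  t <- seq(0, span - 1 / rate, by = 1 / rate)
  with_seed(scenario$seed + 202L, {
    lags <- stats::runif(nrow(schedule), 0.3, 0.5)
    n_blinks <- stats::rpois(1, scenario$blink_rate_hz * span)
    blink_on <- sort(stats::runif(n_blinks, 0, span))
    blink_dur <- stats::rlnorm(n_blinks, log(scenario$blink_median_s),
                               scenario$blink_sdlog)
    noise <- matrix(stats::rnorm(2 * length(t)), ncol = 2)
  })
  eff_onset <- schedule$onset_s + lags
  bias_px <- deg_to_px(scenario$bias_deg, cam) *
    c(cos(scenario$bias_dir_deg * pi / 180),
      sin(scenario$bias_dir_deg * pi / 180))
  noise_px <- deg_to_px(scenario$noise_sd_deg, cam)

  k <- findInterval(t, eff_onset)
  k[k < 1] <- 1  # before the first response the gaze rests on target 1
  # target position per sample, for the label active at that sample
  if (scenario$condition == "walking") {
    b <- motion$bullseye(t)
    gx <- b$x_px; gy <- b$y_px
  } else {
    off <- motion$layout_offset(t)
    li <- match(schedule$label[k], motion$layout$label)
    gx <- motion$layout$x_px[li] + off[, 1]
    gy <- motion$layout$y_px[li] + off[, 2]
  }
  gx <- gx + bias_px[1] + noise_px * noise[, 1]
  gy <- gy + bias_px[2] + noise_px * noise[, 2]
  valid <- rep(TRUE, length(t))
  for (b in seq_along(blink_on))
    valid[t >= blink_on[b] & t < blink_on[b] + blink_dur[b]] <- FALSE
  samples <- data.frame(t = t, x_px = ifelse(valid, gx, NA_real_),
                        y_px = ifelse(valid, gy, NA_real_), valid = valid)
  rec <- gaze_recording(samples, device = scenario$device,
                        rate_hz = rate, camera = cam)
  blink_time <- 0
  if (length(blink_on))
    blink_time <- sum(pmin(blink_on + blink_dur, span) - blink_on)
  list(recording = rec,
       truth = list(bias_deg = scenario$bias_deg, bias_px = bias_px,
                    noise_sd_px = noise_px,
                    lags = data.frame(onset_s = schedule$onset_s,
                                      label = schedule$label, lag_s = lags),
                    blinks = data.frame(onset_s = blink_on,
                                        duration_s = blink_dur),
                    blink_time_s = blink_time, span_s = span))
}

#' Simulate a complete session
#'
#' Protocol, target track and gaze recording from one scenario, fully
#' reproducible from its seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `scenario`, `schedule`, `track`, `recording`,
#'   `truth`.
#' @export
simulate_session <- function(scenario) {
  schedule <- make_protocol(scenario$condition, seed = scenario$seed,
                            spacing_s = scenario$spacing_s,
                            walk_duration_s = scenario$walk_duration_s,
                            turnaround_s = scenario$turnaround_s)
  track <- simulate_target_track(scenario, schedule)
  sim <- simulate_gaze(scenario, track, schedule)
  list(scenario = scenario, schedule = schedule, track = track,
       recording = sim$recording, truth = sim$truth)
}

fill_disk <- function(img, cx, cy, r, col) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- max(1, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dm <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    plane[dm] <- col[ch]
    img[ys, xs, ch] <- plane
  }
  img
}

#' Render one scene-camera frame
#'
#' Produces the synthetic scene image for a target state: nine green
#' disks on a white wall (seated) or a corridor with a red-carpet
#' trapezoid whose straight edges converge at the bullseye, and a
#' concentric-ring bullseye (walking). The rendering is deliberately
#' schematic — flat colors, hard edges — because its purpose is to give
#' the vision module fixtures with exactly known geometry.
#'
#' @param state Data frame of target rows for one frame: columns `label`,
#'   `x_px`, `y_px`, `radius_px` (and `visible` for walking).
#' @param condition Condition name, see [synthetic_scenario()].
#' @param cam A [camera_model()] (sets the image size).
#' @param green,red,wall RGB triplets used for targets, carpet and
#'   background.
#' @param carpet_bottom_width_px Width of the carpet at the bottom image
#'   edge.
#' @return `[height, width, 3]` array in `[0, 1]`.
#' @export
render_frame <- function(state, condition, cam,
                         green = c(0, 0.8, 0), red = c(0.8, 0.12, 0.12),
                         wall = c(1, 1, 1),
                         carpet_bottom_width_px = 900) {
  h <- cam$height_px; w <- cam$width_px
  img <- array(rep(if (condition == "walking") c(0.88, 0.88, 0.88)
                   else wall, each = h * w), c(h, w, 3))
  if (condition == "walking") {
    b <- state[state$label == "bullseye", ][1, ]
    vx <- b$x_px; vy <- b$y_px; r <- b$radius_px
    if (is.finite(vx) && isTRUE(b$visible)) {
      # carpet: region between the two edge lines through the vanishing
      # point, from just below the bullseye center to the bottom edge
      y_top <- max(1, ceiling(vy + 0.5 * r))
      if (y_top < h) {
        ys <- y_top:h
        half <- (carpet_bottom_width_px / 2) * (ys - vy) / (h - vy)
        xl <- pmax(1, ceiling(vx - half))
        xr <- pmin(w, floor(vx + half))
        ok <- xl <= xr
        for (ch in 1:3) {
          plane <- img[, , ch]
          for (i in which(ok))
            plane[ys[i], xl[i]:xr[i]] <- red[ch]
          img[, , ch] <- plane
        }
      }
      ring_cols <- list(green, c(1, 1, 1), green, c(1, 1, 1), green)
      radii <- r * c(1, 0.8, 0.6, 0.4, 0.2)
      for (i in seq_along(radii))
        img <- fill_disk(img, vx, vy, radii[i], ring_cols[[i]])
    }
  } else {
    for (i in seq_len(nrow(state))) {
      if (!is.finite(state$x_px[i])) next
      img <- fill_disk(img, state$x_px[i], state$y_px[i],
                       state$radius_px[i], green)
    }
  }
  img
}

#' Render the frames of a simulated session
#'
#' Evaluates the session's continuous target model at each requested
#' frame and renders it with [render_frame()].
#'
#' @param scenario A [synthetic_scenario()].
#' @param schedule An [instruction_schedule()].
#' @param frames Integer vector of frame indices (0-based).
#' @return List of `[h, w, 3]` arrays.
#' @export
render_session_frames <- function(scenario, schedule, frames) {
  motion <- target_motion(scenario, schedule)
  cam <- scenario$camera
  lapply(frames, function(f)
    render_frame(motion$state(f / cam$frame_rate_hz), scenario$condition,
                 cam))
}
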