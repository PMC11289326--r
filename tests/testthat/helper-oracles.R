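# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the angular oracle builds and normalizes 3-D
# vectors explicitly, and the median oracle loops over every window.

# unit-vector angular distance oracle (degrees)
oracle_angle <- function(p, q, cx, cy, vd) {
  u <- c(p[1] - cx, p[2] - cy, vd)
  v <- c(q[1] - cx, q[2] - cy, vd)
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  acos(min(1, max(-1, sum(u * v)))) * 180 / pi
}

# explicit sliding median over every window, omitting NAs
oracle_sliding_median <- function(x, before, after) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - before):min(n, i + after)]
    w <- w[!is.na(w)]
    if (length(w)) out[i] <- median(w)
  }
  out
}

# textbook paired t
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1))
}

# point-biserial r from the grouped-means formula
oracle_point_biserial <- function(x, y) {
  y1 <- y[x == 1]; y0 <- y[x == 0]
  n <- length(y)
  sn <- sd(y) * sqrt((n - 1) / n)  # population SD, per the textbook formula
  (mean(y1) - mean(y0)) / sn * sqrt(length(y1) * length(y0) / n^2)
}

# sums-of-squares decomposition for the 2x3 within-subject ANOVA via
# stats::aov with an Error() stratum (an independent implementation)
oracle_rm_anova <- function(df) {
  df$participant <- factor(df$participant)
  df$device <- factor(df$device)
  df$dynamicity <- factor(df$dynamicity)
  fit <- stats::aov(value ~ device * dynamicity +
                      Error(participant / (device * dynamicity)), data = df)
  s <- summary(fit)
  get_eff <- function(stratum, row) {
    tab <- s[[stratum]][[1]]
    list(F = tab[row, "F value"], df1 = tab[row, "Df"],
         df2 = tab[nrow(tab), "Df"], p = tab[row, "Pr(>F)"],
         pes = tab[row, "Sum Sq"] /
           (tab[row, "Sum Sq"] + tab[nrow(tab), "Sum Sq"]))
  }
  list(device = get_eff("Error: participant:device", 1),
       dynamicity = get_eff("Error: participant:dynamicity", 1),
       interaction = get_eff("Error: participant:device:dynamicity", 1))
}

# frame-gaze table with a static central target plus bias/noise, for
# estimator-recovery tests (noise injected at the frame level)
make_recovery_case <- function(cam, bias_deg, noise_sd_deg, n_frames = 250,
                               dir_deg = 30) {
  cx <- cam$width_px / 2; cy <- cam$height_px / 2
  bias_px <- deg_to_px(bias_deg, cam) *
    c(cos(dir_deg * pi / 180), sin(dir_deg * pi / 180))
  noise_px <- deg_to_px(noise_sd_deg, cam)
  frames <- data.frame(
    frame = 0:(n_frames - 1), t = (0:(n_frames - 1)) / cam$frame_rate_hz,
    x_px = cx + bias_px[1] + rnorm(n_frames, 0, noise_px),
    y_px = cy + bias_px[2] + rnorm(n_frames, 0, noise_px),
    missing = FALSE)
  class(frames) <- c("frame_gaze", "data.frame")
  track <- target_track(data.frame(
    frame = 0:(n_frames - 1), label = "center", x_px = cx, y_px = cy,
    detected = TRUE))
  interval <- data.frame(start_t = 0, end_t = n_frames / cam$frame_rate_hz,
                         label = "center", kind = "seated")
  list(frames = frames, track = track, interval = interval)
}

# render a 9-dot pose directly from pattern geometry (bypasses the
# scenario machinery so pose parameters are explicit)
render_pose <- function(cam, tx = 0, ty = 0, scale = 1, roll_deg = 0,
                        ring_px = 300, dot_px = 11) {
  ang <- (0:7) * 45 * pi / 180 + roll_deg * pi / 180
  cx <- cam$width_px / 2 + tx; cy <- cam$height_px / 2 + ty
  state <- data.frame(
    label = dot_labels(),
    x_px = cx + c(0, cos(ang) * ring_px * scale),
    y_px = cy + c(0, -sin(ang) * ring_px * scale),
    radius_px = dot_px * scale)
  list(state = state,
       frame = render_frame(state, "seated_chinrest", cam))
}
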