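interval_join <- function(frames, track, interval, cam,
                          frame_rate_hz = cam$frame_rate_hz) {
  f_idx <- interval_frames(interval, frame_rate_hz)
  g <- frames[match(f_idx, frames$frame), , drop = FALSE]
  tr <- track[track$label == interval$label, , drop = FALSE]
  tr <- tr[match(f_idx, tr$frame), , drop = FALSE]
  data.frame(frame = f_idx,
             gx = g$x_px, gy = g$y_px,
             gaze_ok = !is.na(g$missing) & !g$missing,
             tx = tr$x_px, ty = tr$y_px,
             target_ok = !is.na(tr$detected) & tr$detected)
}

#' Accuracy of gaze over one analysis interval
#'
#' Computes the per-frame angular distance theta between the
#' frame-averaged gaze point and the localized target (via
#' [angular_distance()]) and summarizes it over the interval: `accuracy_deg`
#' is the mean of theta (always non-negative — this is overall angular
#' error, not bias), `accuracy_median_deg` the median variant that is
#' robust to the occasional very large deviations. Frames with missing
#' gaze or an undetected target are excluded; an undetected target is not
#' an eye-tracking failure.
#'
#' @param frames A `frame_gaze` data frame from [frame_average()].
#' @param track A [target_track()].
#' @param cam A [camera_model()].
#' @param interval One row of an `interval_set`.
#' @return A one-row data frame of class `accuracy_result` with columns
#'   `label`, `start_t`, `end_t`, `accuracy_deg`, `accuracy_median_deg`,
#'   `bias_deg`, `precision_rms_s2s_deg`, `precision_sd_deg`,
#'   `n_frames_valid`, `missing_pct`, `valid` (FALSE when no frame was
#'   usable).
#' @export
interval_accuracy <- function(frames, track, cam, interval) {
  j <- interval_join(frames, track, interval, cam)
  use <- j$gaze_ok & j$target_ok
  theta <- angular_distance(cbind(j$gx, j$gy), cbind(j$tx, j$ty), cam)
  th <- theta[use]
  res <- data.frame(
    label = interval$label, start_t = interval$start_t,
    end_t = interval$end_t,
    accuracy_deg = if (length(th)) mean(th) else NA_real_,
    accuracy_median_deg = if (length(th)) stats::median(th) else NA_real_,
    bias_deg = interval_bias(frames, track, cam, interval),
    n_frames_valid = sum(use),
    missing_pct = 100 * mean(!j$gaze_ok),
    valid = length(th) > 0,
    stringsAsFactors = FALSE)
  prec <- interval_precision(frames, track, cam, interval)
  res$precision_rms_s2s_deg <- prec[["rms_s2s_deg"]]
  res$precision_sd_deg <- prec[["sd_deg"]]
  class(res) <- c("accuracy_result", "data.frame")
  res
}

#' Bias of gaze over one analysis interval
#'
#' The systematic component of the angular error: the mean of the
#' per-frame gaze-minus-target displacement vectors, applied at the image
#' center and converted to degrees through the camera model. Signed
#' per-frame errors cancel, so bias can be misleadingly small compared to
#' accuracy under symmetric noise; it equals accuracy when the offset is
#' constant. Using per-frame displacements (rather than mean gaze vs mean
#' target) keeps the definition meaningful for moving targets.
#'
#' @inheritParams interval_accuracy
#' @return Bias in degrees (`NA` when no frame is usable).
#' @export
interval_bias <- function(frames, track, cam, interval) {
  j <- interval_join(frames, track, interval, cam)
  use <- j$gaze_ok & j$target_ok
  if (!any(use)) return(NA_real_)
  dx <- mean(j$gx[use] - j$tx[use])
  dy <- mean(j$gy[use] - j$ty[use])
  cx <- cam$width_px / 2; cy <- cam$height_px / 2
  angular_distance(c(cx + dx, cy + dy), c(cx, cy), cam)
}

#' Precision of gaze over one analysis interval
#'
#' Two common dispersion measures, reported side by side because the
#' literature has not settled on one: `rms_s2s_deg` is the
#' root-mean-square of angular distances between successive frame gaze
#' points (target-independent sample-to-sample noise), and `sd_deg` the
#' standard deviation of the per-frame angular-error series theta.
#'
#' @inheritParams interval_accuracy
#' @return Named numeric vector `c(rms_s2s_deg, sd_deg)`; `NA`s with fewer
#'   than two usable frames.
#' @export
interval_precision <- function(frames, track, cam, interval) {
  j <- interval_join(frames, track, interval, cam)
  g_ok <- j$gaze_ok
  out <- c(rms_s2s_deg = NA_real_, sd_deg = NA_real_)
  # successive-frame pairs with gaze on both frames
  pair <- which(g_ok[-length(g_ok)] & g_ok[-1])
  if (length(pair) >= 1) {
    step <- angular_distance(cbind(j$gx[pair], j$gy[pair]),
                             cbind(j$gx[pair + 1], j$gy[pair + 1]), cam)
    out[["rms_s2s_deg"]] <- sqrt(mean(step^2))
  }
  use <- g_ok & j$target_ok
  if (sum(use) >= 2) {
    theta <- angular_distance(cbind(j$gx[use], j$gy[use]),
                              cbind(j$tx[use], j$ty[use]), cam)
    out[["sd_deg"]] <- stats::sd(theta)
  }
  out
}

#' Mean angular speed of the target
#'
#' Instantaneous speed between successive detected target frames —
#' angular distance through the camera model times the frame rate —
#' averaged over the interval. Separates wearer movement (which alone
#' moves the target in the scene image) from eye-tracker error.
#'
#' @param track A [target_track()].
#' @param cam A [camera_model()].
#' @param interval One row of an `interval_set`.
#' @return Mean speed in degrees per second (`NA` with < 2 detections).
#' @export
target_speed <- function(track, cam, interval) {
  f_idx <- interval_frames(interval, cam$frame_rate_hz)
  tr <- track[track$label == interval$label, , drop = FALSE]
  tr <- tr[match(f_idx, tr$frame), , drop = FALSE]
  ok <- !is.na(tr$detected) & tr$detected
  pair <- which(ok[-length(ok)] & ok[-1])
  if (length(pair) < 1) return(NA_real_)
  step <- angular_distance(cbind(tr$x_px[pair], tr$y_px[pair]),
                           cbind(tr$x_px[pair + 1], tr$y_px[pair + 1]), cam)
  mean(step) * cam$frame_rate_hz
}

#' Spatial heatmap of image points
#'
#' Bins points (e.g. target locations across all analysis intervals) into
#' square cells tiling the camera image and normalizes the counts so all
#' cells sum to 1000. Out-of-bounds points are dropped with a message
#' recording the count.
#'
#' @param x_px,y_px Point coordinates in pixels (`(1,1)` = top-left).
#' @param cam A [camera_model()].
#' @param cell_px Cell edge length in pixels (default 20, giving a 54 x 96
#'   grid at 1920 x 1080).
#' @param total Normalization total (default 1000).
#' @return Object of class `gaze_heatmap`: list with `grid` (matrix, rows
#'   = image rows top to bottom), `cell_px`, `n_dropped`.
#' @export
heatmap_from_points <- function(x_px, y_px, cam, cell_px = 20,
                                total = 1000) {
  stopifnot(length(x_px) == length(y_px))
  keep <- is.finite(x_px) & is.finite(y_px) &
    x_px > 0 & x_px <= cam$width_px & y_px > 0 & y_px <= cam$height_px
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("no in-bounds points to bin", call. = FALSE)
  if (n_dropped)
    message(n_dropped, " out-of-bounds point(s) dropped from heatmap")
  nc <- ceiling(cam$width_px / cell_px)
  nr <- ceiling(cam$height_px / cell_px)
  col <- pmin(ceiling(x_px[keep] / cell_px), nc)
  row <- pmin(ceiling(y_px[keep] / cell_px), nr)
  counts <- matrix(0, nr, nc)
  tab <- table(factor(row, levels = 1:nr), factor(col, levels = 1:nc))
  counts[] <- as.numeric(tab)
  structure(list(grid = counts * total / sum(counts), cell_px = cell_px,
                 n_dropped = n_dropped),
            class = "gaze_heatmap")
}

#' Summarize accuracy results across participants
#'
#' Collapses per-interval results to per-participant means within each
#' group, then reports the mean, SD and median across participants — the
#' layout of a per-condition results table. Supports the "all dots" /
#' "only central dot" split via `labels`.
#'
#' @param results Data frame of per-interval rows including columns
#'   `participant`, `device`, `condition`, `label` and the metric column.
#' @param metric Name of the metric column to summarize (default
#'   `"accuracy_deg"`).
#' @param by Grouping columns (default device and condition).
#' @param labels Optional label filter, e.g. `"center"`.
#' @return Data frame with one row per group: `mean`, `sd`, `median`, `n`
#'   (number of participants). A single-participant group reports `sd = 0`
#'   and `sd_defined = FALSE`.
#' @export
condition_summary <- function(results, metric = "accuracy_deg",
                              by = c("device", "condition"),
                              labels = NULL) {
  stopifnot(all(c("participant", metric) %in% names(results)))
  if (!is.null(labels)) results <- results[results$label %in% labels, ,
                                           drop = FALSE]
  if (nrow(results) == 0) stop("no rows to summarize", call. = FALSE)
  key <- interaction(results[by], drop = TRUE, sep = " / ")
  out <- lapply(levels(key), function(k) {
    sub <- results[key == k, , drop = FALSE]
    per_part <- tapply(sub[[metric]], sub$participant,
                       function(v) mean(v, na.rm = TRUE))
    per_part <- per_part[is.finite(per_part)]
    if (!length(per_part)) {
      warning("group '", k, "' has no usable participants; omitted",
              call. = FALSE)
      return(NULL)
    }
    grp <- sub[1, by, drop = FALSE]
    cbind(grp,
          data.frame(mean = mean(per_part),
                     sd = if (length(per_part) > 1) stats::sd(per_part) else 0,
                     sd_defined = length(per_part) > 1,
                     median = stats::median(per_part),
                     n = length(per_part)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
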