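#' Instruction onsets from an audio envelope
#'
#' Finds rising threshold crossings of a non-negative audio envelope,
#' enforcing a refractory period so each instruction burst contributes one
#' onset. Schedules read from file are the primary input for segmentation;
#' this extractor exists for sessions where only the glasses' audio track
#' carries the instruction timing.
#'
#' @param envelope Non-negative numeric vector (rectified/low-passed audio).
#' @param rate_hz Sampling rate of the envelope.
#' @param threshold Crossing threshold.
#' @param refractory_s Minimum separation between onsets in seconds.
#' @return Numeric vector of onset times in seconds (possibly empty).
#' @export
onsets_from_audio <- function(envelope, rate_hz, threshold,
                              refractory_s = 1) {
  stopifnot(all(envelope >= 0), rate_hz > 0, threshold > 0)
  above <- envelope >= threshold
  rising <- which(above & !c(FALSE, above[-length(above)]))
  onsets <- numeric(0)
  last <- -Inf
  for (i in rising) {
    t <- (i - 1) / rate_hz
    if (t - last >= refractory_s) {
      onsets <- c(onsets, t)
      last <- t
    }
  }
  onsets
}

#' Analysis intervals for a seated trial
#'
#' One 10-second window per instruction: the first `skip_s` seconds after
#' each onset are discarded (time to refocus on the new dot) and the
#' window covers the following `window_s` seconds — 250 video frames at
#' 25 fps. If the next instruction arrives before the window ends, the
#' window is truncated there with a warning.
#'
#' @param schedule An [instruction_schedule()].
#' @param skip_s Seconds discarded after each onset (default 2).
#' @param window_s Window length in seconds (default 10).
#' @return Data frame of class `interval_set` with columns `start_t`,
#'   `end_t`, `label`, `kind`.
#' @export
seated_intervals <- function(schedule, skip_s = 2, window_s = 10) {
  stopifnot(inherits(schedule, "instruction_schedule"))
  if (nrow(schedule) == 0) stop("empty schedule", call. = FALSE)
  on <- schedule$onset_s
  start_t <- on + skip_s
  end_t <- on + skip_s + window_s
  nxt <- c(on[-1], Inf)
  trunc <- end_t > nxt
  if (any(trunc)) {
    warning(sum(trunc), " interval(s) truncated by the next instruction",
            call. = FALSE)
    end_t[trunc] <- nxt[trunc]
  }
  if (any(end_t <= start_t))
    stop("instruction spacing leaves no analysis window", call. = FALSE)
  out <- data.frame(start_t = start_t, end_t = end_t,
                    label = schedule$label, kind = "seated",
                    stringsAsFactors = FALSE)
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Analysis intervals for a walking trial
#'
#' Each walk's window ends approximately when the red carpet leaves the
#' scene camera's view and starts 10 seconds before that. The end point is
#' the last frame with the carpet visible before a sustained (>
#' `sustained_s`) run of invisibility; single-frame detection dropouts do
#' not end a walk. Without any sustained invisibility the fallback is one
#' window ending at the last visible frame. At most `max_walks` windows
#' are returned.
#'
#' @param track A [target_track()] whose bullseye rows carry a logical
#'   `visible` column (carpet/target visibility per frame).
#' @param window_s Window length in seconds (default 10).
#' @param frame_rate_hz Video frame rate.
#' @param sustained_s Minimum invisibility run that ends a walk (default 2).
#' @param max_walks Maximum number of windows (default 2).
#' @return Data frame of class `interval_set`.
#' @export
walking_intervals <- function(track, window_s = 10, frame_rate_hz = 25,
                              sustained_s = 2, max_walks = 2) {
  stopifnot(inherits(track, "target_track"))
  sub <- track[track$label == "bullseye", , drop = FALSE]
  if (!"visible" %in% names(sub) || nrow(sub) == 0)
    stop("walking track needs bullseye rows with a 'visible' column",
         call. = FALSE)
  sub <- sub[order(sub$frame), ]
  vis <- sub$visible
  r <- rle(!vis)
  ends_idx <- integer(0)
  pos <- cumsum(r$lengths)
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] > sustained_s * frame_rate_hz && k > 1)
      ends_idx <- c(ends_idx, pos[k - 1])
  }
  if (!length(ends_idx)) {
    last_vis <- max(which(vis))
    ends_idx <- last_vis
  } else if (r$values[length(r$values)] == FALSE && any(vis)) {
    # recording ends while still visible: that walk ends at the last frame
    ends_idx <- c(ends_idx, length(vis))
  }
  ends_idx <- utils::head(ends_idx, max_walks)
  end_t <- (sub$frame[ends_idx] + 1) / frame_rate_hz
  out <- data.frame(start_t = end_t - window_s, end_t = end_t,
                    label = "bullseye", kind = "walking",
                    stringsAsFactors = FALSE)
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Frames covered by an interval
#'
#' The inclusive frame-index range of an analysis window: frames `f` with
#' start time `f / fps` in `[start_t, end_t)` — exactly
#' `window_s * fps` (250) frames for an untruncated window.
#'
#' @param interval One row of an `interval_set`.
#' @param frame_rate_hz Video frame rate.
#' @return Integer vector of frame indices.
#' @export
interval_frames <- function(interval, frame_rate_hz = 25) {
  f0 <- ceiling(interval$start_t * frame_rate_hz - 1e-9)
  f1 <- ceiling(interval$end_t * frame_rate_hz - 1e-9) - 1
  seq.int(f0, f1)
}
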