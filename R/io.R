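#' Gaze recording container
#'
#' A time-ordered sequence of gaze samples from one trial, together with
#' the device label, nominal sampling rate and the scene-camera model.
#' Samples are stored as a data frame with columns `t` (seconds from
#' recording start), `x_px`, `y_px` (gaze point in scene-camera pixels),
#' `valid` (logical) and optionally `pupil_mm`. Invalid samples keep their
#' row (with `NA` coordinates) so that missing-data accounting stays exact.
#'
#' @param samples Data frame with columns `t`, `x_px`, `y_px`, and
#'   optionally `valid` and `pupil_mm`. Rows with `NA` coordinates are
#'   marked invalid automatically.
#' @param device Device label, `"tobii2"` or `"tobii3"` (or any string for
#'   a custom device when `rate_hz` and `camera` are given explicitly).
#' @param rate_hz Nominal sampling rate; defaults to the device profile.
#' @param camera A [camera_model()]; defaults to the device profile.
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, device = "tobii2", rate_hz = NULL,
                           camera = NULL) {
  if (device %in% c("tobii2", "tobii3")) {
    prof <- device_profile(device)
    if (is.null(rate_hz)) rate_hz <- prof$rate_hz
    if (is.null(camera)) camera <- prof$camera
  }
  if (is.null(rate_hz) || is.null(camera))
    stop("`rate_hz` and `camera` are required for custom devices",
         call. = FALSE)
  stopifnot(is.data.frame(samples),
            all(c("t", "x_px", "y_px") %in% names(samples)))
  if (!"valid" %in% names(samples))
    samples$valid <- is.finite(samples$x_px) & is.finite(samples$y_px)
  samples$valid <- samples$valid & is.finite(samples$x_px) &
    is.finite(samples$y_px)
  samples$x_px[!samples$valid] <- NA_real_
  samples$y_px[!samples$valid] <- NA_real_
  if (any(!is.finite(samples$t)))
    stop("sample timestamps must be finite", call. = FALSE)
  if (is.unsorted(samples$t, strictly = TRUE))
    stop("sample timestamps must be strictly increasing", call. = FALSE)
  if ("pupil_mm" %in% names(samples) &&
      any(samples$pupil_mm <= 0, na.rm = TRUE))
    stop("pupil_mm must be positive when present", call. = FALSE)
  rownames(samples) <- NULL
  structure(list(device = device, rate_hz = rate_hz,
                 samples = samples, camera = camera),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf(
    "<gaze_recording> %s @ %g Hz: %d samples over %.2f s (%.1f%% invalid)\n",
    x$device, x$rate_hz, n,
    if (n) diff(range(x$samples$t)) else 0,
    if (n) 100 * mean(!x$samples$valid) else 0))
  invisible(x)
}

#' Read a gaze export table
#'
#' Parses a delimited gaze export into a [gaze_recording()]. Rows whose
#' gaze-point cells are empty or non-numeric become invalid samples — they
#' are retained, not dropped, so frame-level missing-data fractions remain
#' meaningful. Column names vary between device software versions, so the
#' mapping is configurable; the defaults follow the common export layout.
#'
#' @param path Path to a CSV/TSV file.
#' @param device Device label passed to [gaze_recording()].
#' @param columns Named list mapping the roles `t`, `x`, `y` and optionally
#'   `pupil` to column names in the file.
#' @param t_unit Unit of the timestamp column: `"s"`, `"ms"` or `"us"`;
#'   timestamps are normalized to seconds from the first sample.
#' @param sep Field separator (`","` or `"\t"`).
#' @param rate_hz,camera Optional overrides, see [gaze_recording()].
#' @return A [gaze_recording()].
#' @export
read_gaze_export <- function(path, device = "tobii2",
                             columns = list(t = "Timestamp",
                                            x = "Gaze Point X",
                                            y = "Gaze Point Y",
                                            pupil = "Pupil Diameter"),
                             t_unit = c("s", "ms", "us"),
                             sep = ",", rate_hz = NULL, camera = NULL) {
  t_unit <- match.arg(t_unit)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA", "NaN"))
  for (role in c("t", "x", "y")) {
    col <- columns[[role]]
    if (is.null(col) || !col %in% names(raw))
      stop(sprintf("gaze export is missing required column '%s' (role '%s')",
                   if (is.null(col)) "<unmapped>" else col, role),
           call. = FALSE)
  }
  scale <- c(s = 1, ms = 1e-3, us = 1e-6)[[t_unit]]
  t <- as.numeric(raw[[columns$t]]) * scale
  if (anyNA(t)) stop("non-numeric timestamps in gaze export", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("gaze export timestamps are not strictly increasing", call. = FALSE)
  samples <- data.frame(
    t = t - t[1],
    x_px = suppressWarnings(as.numeric(raw[[columns$x]])),
    y_px = suppressWarnings(as.numeric(raw[[columns$y]])))
  if (!is.null(columns$pupil) && columns$pupil %in% names(raw))
    samples$pupil_mm <- suppressWarnings(as.numeric(raw[[columns$pupil]]))
  gaze_recording(samples, device = device, rate_hz = rate_hz, camera = camera)
}

#' Write a gaze recording back to a delimited export
#'
#' Inverse of [read_gaze_export()]; round trips are lossless for the
#' mapped columns.
#'
#' @inheritParams read_gaze_export
#' @param rec A [gaze_recording()].
#' @export
write_gaze_export <- function(rec, path,
                              columns = list(t = "Timestamp",
                                             x = "Gaze Point X",
                                             y = "Gaze Point Y",
                                             pupil = "Pupil Diameter"),
                              sep = ",") {
  stopifnot(inherits(rec, "gaze_recording"))
  out <- data.frame(rec$samples$t, rec$samples$x_px, rec$samples$y_px,
                    check.names = FALSE)
  names(out) <- c(columns$t, columns$x, columns$y)
  if ("pupil_mm" %in% names(rec$samples))
    out[[columns$pupil]] <- rec$samples$pupil_mm
  utils::write.table(out, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

#' Instruction schedule
#'
#' The ordered list of audio-instruction onsets and the target label each
#' instruction directs the wearer's gaze to. The seated protocol has 19
#' entries (the central dot three times — first, middle and last — and the
#' eight peripheral dots twice each); walking protocols carry one entry
#' per walk epoch, labelled `"bullseye"`.
#'
#' @param onset_s Numeric vector of strictly increasing onset times (s).
#' @param label Character vector of target labels.
#' @return A data frame of class `instruction_schedule`.
#' @export
instruction_schedule <- function(onset_s, label) {
  stopifnot(length(onset_s) == length(label), length(onset_s) >= 1)
  if (is.unsorted(onset_s, strictly = TRUE))
    stop("instruction onsets must be strictly increasing", call. = FALSE)
  bad <- setdiff(label, c(dot_labels(), "bullseye"))
  if (length(bad))
    stop("unknown target label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(data.frame(onset_s = as.numeric(onset_s),
                       label = as.character(label)),
            class = c("instruction_schedule", "data.frame"))
}

#' The nine seated-target labels
#'
#' Center plus the eight compass directions, in the order used for sector
#' labelling (counter-clockwise from "right" in image coordinates).
#' @return Character vector of length 9.
#' @export
dot_labels <- function() {
  c("center", "right", "top-right", "top", "top-left",
    "left", "bottom-left", "bottom", "bottom-right")
}

#' Read / write instruction schedules
#'
#' CSV with columns `onset_s,label`.
#' @param path File path.
#' @return [instruction_schedule()] for the reader; `path` invisibly for
#'   the writer.
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "label") %in% names(df)))
    stop("schedule file must have columns onset_s,label", call. = FALSE)
  instruction_schedule(df$onset_s, df$label)
}

#' @rdname read_schedule
#' @param schedule An [instruction_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule)[, c("onset_s", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Frame-sequence reader
#'
#' Opens a scene-video frame source: a directory of numbered PNG images
#' (`frame_000001.png`, ...). Frames are read lazily; timestamps are
#' `index / frame_rate` with the first frame at index 0. Unreadable frames
#' are skipped with a warning, leaving a gap in the index sequence; mixed
#' resolutions raise an error at read time.
#'
#' @param path Directory containing numbered `.png` frames.
#' @param frame_rate_hz Frames per second (default 25).
#' @return An object of class `frame_source` with fields `n`, `index`
#'   (0-based frame indices), `t` (seconds) and function `frame(i)`
#'   returning the i-th available frame as an `[height, width, 3]` array
#'   in `[0, 1]`.
#' @export
read_frames <- function(path, frame_rate_hz = 25) {
  stopifnot(dir.exists(path))
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  ok <- rep(TRUE, length(files))
  dims <- NULL
  for (i in seq_along(files)) {
    hdr <- tryCatch(png_dim(files[i]), error = function(e) NULL)
    if (is.null(hdr)) {
      warning("skipping unreadable frame: ", basename(files[i]),
              call. = FALSE)
      ok[i] <- FALSE
      next
    }
    if (is.null(dims)) dims <- hdr
    else if (!identical(dims, hdr))
      stop("mixed frame resolutions in ", path, call. = FALSE)
  }
  files <- files[ok]
  index <- as.integer(sub("\\D*(\\d+)\\.png$", "\\1", basename(files)))
  if (anyNA(index)) index <- seq_along(files) - 1L
  structure(list(
    n = length(files),
    index = index,
    t = index / frame_rate_hz,
    files = files,
    frame = function(i) {
      img <- png::readPNG(files[i])
      if (length(dim(img)) == 2) stop("grayscale frame", call. = FALSE)
      img[, , 1:3, drop = FALSE]
    }),
    class = "frame_source")
}

png_dim <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  dim(img)[1:2]
}

#' Write a frame sequence as numbered PNGs
#'
#' @param frames List of `[h, w, 3]` arrays in `[0, 1]`.
#' @param dir Output directory (created if needed).
#' @param start_index Index of the first frame (default 0).
#' @return The directory, invisibly.
#' @export
write_frames <- function(frames, dir, start_index = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]],
                  file.path(dir, sprintf("frame_%06d.png",
                                         start_index + i - 1)))
  }
  invisible(dir)
}

#' Read / write a heatmap grid as CSV
#'
#' Plain rectangular CSV of cell weights, row 1 = top image row.
#' @param hm A `gaze_heatmap` (see [heatmap_from_points()]).
#' @param path File path.
#' @export
write_heatmap_csv <- function(hm, path) {
  stopifnot(inherits(hm, "gaze_heatmap"))
  utils::write.table(unclass(hm$grid), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_csv
#' @param cell_px Cell size in pixels (metadata for the reconstructed
#'   object).
#' @export
read_heatmap_csv <- function(path, cell_px = 20) {
  grid <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(grid) <- NULL
  structure(list(grid = grid, cell_px = cell_px), class = "gaze_heatmap")
}
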