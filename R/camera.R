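#' Scene-camera model
#'
#' Describes the forward-facing scene camera of a pair of eye-tracking
#' glasses. Gaze and target positions are expressed in its pixel
#' coordinates, with `(1, 1)` the top-left corner, x increasing rightward
#' and y increasing downward. The virtual viewing distance `vd_px` is the
#' camera's magnification expressed as a distance in pixels: the ratio of
#' the physical camera-to-wall distance to the physical footprint of one
#' pixel on the wall. It converts pixel offsets from the image center into
#' visual angles.
#'
#' @param width_px,height_px Image resolution in pixels.
#' @param vd_px Virtual viewing distance in pixels (> 0).
#' @param frame_rate_hz Scene-video frame rate (frames per second).
#' @param pitch_deg Downward pitch of the scene camera relative to the
#'   wearer's line of sight, in degrees. Recorded metadata; it shifts where
#'   targets appear in the image but enters no angular computation.
#'
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(vd_px = 1132.4)
#' cam$width_px / 2  # image-center x used by angular_distance()
#' @export
camera_model <- function(width_px = 1920, height_px = 1080, vd_px,
                         frame_rate_hz = 25, pitch_deg = 0) {
  stopifnot(is.numeric(vd_px), length(vd_px) == 1, is.finite(vd_px),
            vd_px > 0, width_px > 0, height_px > 0, frame_rate_hz > 0)
  structure(
    list(width_px = as.numeric(width_px), height_px = as.numeric(height_px),
         vd_px = as.numeric(vd_px), frame_rate_hz = as.numeric(frame_rate_hz),
         pitch_deg = as.numeric(pitch_deg)),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %gx%g px @ %g fps, VD = %g px, pitch = %g deg\n",
              x$width_px, x$height_px, x$frame_rate_hz, x$vd_px, x$pitch_deg))
  invisible(x)
}

#' Built-in device profiles
#'
#' Camera models and sampling rates for the two supported glasses-type
#' eye-trackers: a 50-Hz device with a strongly pitched scene camera
#' (`"tobii2"`) and a 100-Hz device with a wider field of view
#' (`"tobii3"`). Virtual viewing distances are the calibrated values
#' recovered from graph-paper measurements at roughly 1 m from a wall.
#'
#' @param device `"tobii2"` or `"tobii3"`.
#' @return A list with elements `device`, `rate_hz` and `camera`.
#' @export
device_profile <- function(device = c("tobii2", "tobii3")) {
  device <- match.arg(device)
  switch(device,
    tobii2 = list(device = "tobii2", rate_hz = 50,
                  camera = camera_model(vd_px = 1132.4, pitch_deg = 12)),
    tobii3 = list(device = "tobii3", rate_hz = 100,
                  camera = camera_model(vd_px = 912.8, pitch_deg = 1))
  )
}

#' Angular distance between two image points
#'
#' The angle, at the camera, between the rays through two pixel
#' coordinates. Each point is referred to the image center and lifted to a
#' 3-D vector `(x - cx, y - cy, VD)`; the angle is the arc-cosine of the
#' normalized dot product of the two vectors. This is the per-frame angular
#' error theta when one point is the recorded gaze and the other the
#' localized target.
#'
#' Vectorized over points; any non-finite coordinate yields `NA` for that
#' element (missing data propagate, they are never fabricated).
#'
#' @param p,q Points in pixels: length-2 vectors `c(x, y)`, or two-column
#'   matrices / data frames with one row per point.
#' @param cam A [camera_model()].
#' @return Angular distance(s) in degrees, in `[0, 180)`.
#' @examples
#' cam <- camera_model(vd_px = 1132.4)
#' angular_distance(c(560, 540), c(960, 540), cam)  # ~19.5 degrees
#' @export
angular_distance <- function(p, q, cam) {
  stopifnot(inherits(cam, "camera_model"))
  p <- as_xy_matrix(p)
  q <- as_xy_matrix(q)
  n <- max(nrow(p), nrow(q))
  if (nrow(p) == 1 && n > 1) p <- p[rep(1, n), , drop = FALSE]
  if (nrow(q) == 1 && n > 1) q <- q[rep(1, n), , drop = FALSE]
  stopifnot(nrow(p) == nrow(q))
  cx <- cam$width_px / 2
  cy <- cam$height_px / 2
  vd <- cam$vd_px
  u1 <- p[, 1] - cx; v1 <- p[, 2] - cy
  u2 <- q[, 1] - cx; v2 <- q[, 2] - cy
  dot <- u1 * u2 + v1 * v2 + vd^2
  # the arc-cosine of the normalized dot product loses ~1e-7 deg near
  # zero; atan2(|u x v|, u.v) is the same angle, evaluated stably
  cr1 <- v1 * vd - v2 * vd
  cr2 <- vd * u2 - vd * u1
  cr3 <- u1 * v2 - u2 * v1
  theta <- atan2(sqrt(cr1^2 + cr2^2 + cr3^2), dot) * 180 / pi
  theta[!is.finite(p[, 1]) | !is.finite(p[, 2]) |
        !is.finite(q[, 1]) | !is.finite(q[, 2])] <- NA_real_
  theta
}

as_xy_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) {
    stopifnot(length(p) == 2)
    p <- matrix(as.numeric(p), ncol = 2)
  }
  stopifnot(ncol(p) == 2)
  storage.mode(p) <- "double"
  p
}

#' Convert a physical on-wall distance to a visual angle
#'
#' `atan(d / D)` in degrees, where `d` is the distance of a point from the
#' image-center projection on the wall and `D` the camera-to-wall distance,
#' both in millimetres.
#'
#' @param d_mm On-wall distance(s) from the center point, in mm (>= 0).
#' @param D_mm Camera-to-wall distance in mm (> 0).
#' @return Angle(s) in degrees.
#' @export
mm_to_deg <- function(d_mm, D_mm) {
  if (!is.numeric(D_mm) || any(!is.finite(D_mm)) || any(D_mm <= 0))
    stop("`D_mm` must be a positive finite distance", call. = FALSE)
  stopifnot(is.numeric(d_mm), all(d_mm >= 0))
  atan(d_mm / D_mm) * 180 / pi
}

#' Calibration measurement for virtual-viewing-distance estimation
#'
#' Measurements taken with the glasses facing graph paper on a wall: the
#' camera-to-wall distance `D`, and for several image points at a known
#' pixel eccentricity from the image center, the physical distance `d` of
#' their on-wall projection from the center (read off the grid).
#'
#' @param D_mm Camera-to-wall distance in mm (> 0).
#' @param offsets Data frame with columns `point_x`, `point_y` (pixel
#'   coordinates of the measured points) and `distance_mm` (their on-wall
#'   distance from the center, > 0), or a bare numeric vector of distances.
#' @param eccentricity_px Nominal radial pixel eccentricity shared by the
#'   measured points (e.g. 400).
#' @return An object of class `calibration_measurement`.
#' @export
calibration_measurement <- function(D_mm, offsets, eccentricity_px = 400) {
  if (is.numeric(offsets))
    offsets <- data.frame(point_x = NA_real_, point_y = NA_real_,
                          distance_mm = as.numeric(offsets))
  stopifnot(is.data.frame(offsets), nrow(offsets) >= 1,
            "distance_mm" %in% names(offsets))
  if (!is.numeric(D_mm) || D_mm <= 0) stop("`D_mm` must be > 0", call. = FALSE)
  if (any(offsets$distance_mm <= 0))
    stop("all offset distances must be > 0", call. = FALSE)
  stopifnot(eccentricity_px > 0)
  structure(list(D_mm = as.numeric(D_mm), offsets = offsets,
                 eccentricity_px = as.numeric(eccentricity_px)),
            class = "calibration_measurement")
}

#' Estimate the virtual viewing distance from calibration offsets
#'
#' `VD = eccentricity_px * D / mean(d)`: the pixel eccentricity divided by
#' the tangent of the mean angle subtended by the measured points.
#'
#' @param cal A [calibration_measurement()].
#' @return The virtual viewing distance in pixels.
#' @examples
#' cal <- calibration_measurement(1010, c(357, 358, 354, 358))
#' estimate_vd(cal)  # ~1132.4 px
#' @export
estimate_vd <- function(cal) {
  stopifnot(inherits(cal, "calibration_measurement"))
  md <- mean(cal$offsets$distance_mm)
  if (md == 0) stop("mean offset distance is zero", call. = FALSE)
  cal$eccentricity_px * cal$D_mm / md
}

#' Field of view from edge-to-center distances
#'
#' The full field of view along one image axis, from the on-wall distances
#' of the two opposite image edges to the center point. Each half-angle is
#' converted with [mm_to_deg()], rounded to `digits` decimals, and the two
#' rounded half-angles are summed — mirroring how per-edge angles are
#' typically tabulated to one decimal before being added.
#'
#' @param left_mm,right_mm On-wall distances (mm) from the center to the
#'   two opposite edges of the image along the axis.
#' @param D_mm Camera-to-wall distance in mm.
#' @param digits Decimals each half-angle is rounded to before summing.
#' @return Field of view in degrees.
#' @examples
#' fov_from_edges(846, 850, 1010)  # 80.1 (horizontal)
#' fov_from_edges(475, 481, 1010)  # 50.7 (vertical)
#' @export
fov_from_edges <- function(left_mm, right_mm, D_mm, digits = 1) {
  stopifnot(left_mm > 0, right_mm > 0)
  round(mm_to_deg(left_mm, D_mm), digits) +
    round(mm_to_deg(right_mm, D_mm), digits)
}

#' Pixel/degree conversions through the camera model
#'
#' Small helpers used throughout the package: `deg_to_px()` returns the
#' pixel offset from the image center subtending a given angle
#' (`VD * tan(angle)`), and `px_to_deg()` its inverse (`atan(px / VD)`).
#'
#' @param deg,px Angles in degrees / radial pixel offsets from center.
#' @param cam A [camera_model()].
#' @return Numeric vector.
#' @export
deg_to_px <- function(deg, cam) cam$vd_px * tan(deg * pi / 180)

#' @rdname deg_to_px
#' @export
px_to_deg <- function(px, cam) atan(px / cam$vd_px) * 180 / pi
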