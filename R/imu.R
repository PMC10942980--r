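# Sagittal segment angles from IMU orientation quaternions.
#
# Two calibration schemes are implemented:
#
# * static_pose: orientations are referenced to the mean orientation over a
#   standing window, and the angle is extracted about the mediolateral axis
#   frozen at calibration. Simple, but any heading drift the fused orientation
#   accumulates about gravity leaks into the angle over time.
#
# * per_frame: at every sample the global frame is rebuilt with one axis along
#   the (horizontally projected) joint axis and another against gravity, and
#   the sagittal angle is the Euler angle about the joint axis in that frame.
#   Because the frame is rebuilt from the current joint-axis direction, any
#   rotation about gravity -- static heading offset or accumulating drift --
#   is annihilated exactly for planar (hinge-joint) motion.
#
# Assumptions shared with the modeling of running used here: hips, knees and
# ankles act as hinge joints, so segment motion is sagittal and one sensor
# axis (known from mounting) stays aligned with the joint axis.

imu_quaternions <- function(trial) {
  q <- as.matrix(trial$data[c("q_w", "q_x", "q_y", "q_z")])
  quat_continuous(quat_normalize(q))
}

# Remove 360-degree jumps from an angle series. The raw extracted angle can
# sit near +/-180 degrees when the sensor is mounted with a flipped or spun
# axis, so the atan2 branch cut may be crossed during motion; unwrapping keeps
# the series continuous before the constant offset is removed.
unwrap_deg <- function(theta) {
  d <- diff(theta)
  adj <- cumsum(ifelse(d > 180, -360, ifelse(d < -180, 360, 0)))
  theta + c(0, adj)
}

# Complete the local joint axis into a frame; only the third axis is needed by
# the extraction. Candidate order e3, e1, e2 with a fixed tie-break.
local_third_axis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  for (u in list(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))) {
    if (abs(sum(u * axis)) < 0.9) {
      z <- u - sum(u * axis) * axis
      return(z / sqrt(sum(z^2)))
    }
  }
  stop("degenerate joint axis")
}

#' Calibrate an IMU's mounting from a standing pose
#'
#' Averages the sensor orientation (quaternion barycenter via the principal
#' eigenvector, sign-flip invariant) over a quiet standing window and stores
#' it together with the sensor-frame joint axis. Angles referenced to this
#' calibration are exactly zero at the standing pose: thigh and shank
#' vertical, foot flat.
#'
#' @param trial an IMU [trial_table()] with quaternion (and gyroscope)
#'   channels.
#' @param window length-2 numeric, start and end (s, on the trial's own clock)
#'   of the standing window; at least 0.5 s.
#' @param joint_axis_local unit 3-vector: the joint (mediolateral) axis in the
#'   sensor frame, known from mounting.
#' @param segment segment label (`"thigh"`, `"shank"`, `"foot"`).
#' @param max_gyro largest tolerated gyroscope norm in the window (deg/s).
#' @return A `mounting_info` list: `segment`, `joint_axis_local`,
#'   `static_offset` (1 x 4 quaternion), `window`.
#' @export
static_pose_calibrate <- function(trial, window, joint_axis_local,
                                  segment = c("thigh", "shank", "foot"),
                                  max_gyro = 10) {
  segment <- match.arg(segment)
  if (diff(window) < 0.5) stop("standing window must cover at least 0.5 s")
  sel <- trial$time >= window[1] & trial$time <= window[2]
  if (sum(sel) < 2L) stop("standing window contains no samples")
  gyro_cols <- c("gyro_x", "gyro_y", "gyro_z")
  if (all(gyro_cols %in% names(trial$data))) {
    g <- as.matrix(trial$data[gyro_cols])[sel, , drop = FALSE]
    gn <- sqrt(rowSums(g^2))
    if (any(gn >= max_gyro)) {
      stop(sprintf("motion detected in standing window (gyro norm %.1f deg/s >= %g)",
                   max(gn), max_gyro))
    }
  }
  axis <- joint_axis_local / sqrt(sum(joint_axis_local^2))
  q <- imu_quaternions(trial)[sel, , drop = FALSE]
  structure(list(segment = segment, joint_axis_local = axis,
                 static_offset = quat_mean(q), window = window),
            class = "mounting_info")
}

#' Sagittal angle series from IMU orientations
#'
#' Extracts the sagittal segment angle per frame using either the
#' standing-pose calibration (`method = "static_pose"`) or the per-frame
#' global-frame redefinition (`method = "per_frame"`); see the module header
#' for the two schemes. After extraction the series is offset so its mean over
#' the calibration window is zero (standing pose reads 0 degrees; for the foot
#' this sets the flat-foot horizontal reference), and multiplied by `sign` to
#' match the motion-capture convention (distal end forward = positive). The
#' sign is resolved functionally by the caller, e.g. from the signed peak
#' correlation against a reference angle during the calibration maneuver.
#'
#' @param trial an IMU [trial_table()].
#' @param mounting a `mounting_info` from [static_pose_calibrate()].
#' @param method `"per_frame"` or `"static_pose"`.
#' @param reference `"vertical"` (thigh/shank) or `"horizontal"` (foot); label
#'   only, the zero-offset construction already encodes the reference.
#' @param gravity_up unit global up direction of the fused orientations.
#' @param sign +1 or -1.
#' @return An `imu_angle_series`: list with `time`, `theta` (deg), `method`,
#'   `segment`.
#' @export
sagittal_angle_imu <- function(trial, mounting,
                               method = c("per_frame", "static_pose"),
                               reference = c("vertical", "horizontal"),
                               gravity_up = c(0, 0, 1), sign = 1) {
  method <- match.arg(method)
  reference <- match.arg(reference)
  q <- imu_quaternions(trial)
  axis <- mounting$joint_axis_local
  theta <- if (method == "per_frame") {
    sagittal_per_frame(q, axis, gravity_up)
  } else {
    sagittal_static(q, mounting$static_offset, axis, gravity_up)
  }
  theta <- unwrap_deg(theta)
  sel <- trial$time >= mounting$window[1] & trial$time <= mounting$window[2]
  theta <- sign * (theta - mean(theta[sel]))
  structure(list(time = trial$time, theta = theta, method = method,
                 segment = mounting$segment, reference = reference),
            class = "imu_angle_series")
}

# Per-frame reference redefinition. For each sample: project the globalized
# joint axis onto the horizontal plane to get y', take z' = up and
# x' = y' x z', then read the Euler angle about y' from the rotation of the
# local frame completion. Rotations about gravity commute out exactly.
sagittal_per_frame <- function(q, axis_local, up = c(0, 0, 1)) {
  up <- up / sqrt(sum(up^2))
  z_l <- local_third_axis(axis_local)
  a_g <- quat_rotate(q, axis_local)
  vert <- a_g %*% up
  horiz <- a_g - vert %*% t(up)
  h <- sqrt(rowSums(horiz^2))
  if (any(h < sin(5 * pi / 180))) {
    stop(sprintf("joint axis within 5 degrees of vertical at frame %d; frame reconstruction degenerate",
                 which(h < sin(5 * pi / 180))[1]))
  }
  yp <- horiz / h
  v <- quat_rotate(q, z_l)
  # x' = y' x up; M13 = v . x', M33 = v . up
  xp <- cbind(yp[, 2] * up[3] - yp[, 3] * up[2],
              yp[, 3] * up[1] - yp[, 1] * up[3],
              yp[, 1] * up[2] - yp[, 2] * up[1])
  m13 <- rowSums(v * xp)
  m33 <- as.numeric(v %*% up)
  atan2(-m13, m33) * 180 / pi
}

# Standing-pose referenced extraction: rotate the standing "segment down"
# direction by the orientation relative to the standing mean, and measure its
# angle in the sagittal plane frozen at calibration.
sagittal_static <- function(q, q_static, axis_local, up = c(0, 0, 1)) {
  up <- up / sqrt(sum(up^2))
  q_rel <- quat_multiply(q, quat_conjugate(q_static))
  a_g0 <- as.numeric(quat_rotate(q_static, axis_local))
  vert <- sum(a_g0 * up)
  horiz <- a_g0 - vert * up
  h <- sqrt(sum(horiz^2))
  if (h < sin(5 * pi / 180)) {
    stop("calibrated joint axis within 5 degrees of vertical")
  }
  y0 <- horiz / h
  x0 <- c(y0[2] * up[3] - y0[3] * up[2],
          y0[3] * up[1] - y0[1] * up[3],
          y0[1] * up[2] - y0[2] * up[1])
  d <- quat_rotate(q_rel, -up)
  atan2(as.numeric(d %*% x0), -as.numeric(d %*% up)) * 180 / pi
}

#' Interpolate an angle series at foot-contact instants
#'
#' Linear interpolation of the angle series to each foot-contact time. Foot
#' contacts outside the series support are excluded: the returned vector
#' carries `NA` for them and an `excluded` attribute with their indices, and a
#' warning reports how many strides were dropped.
#'
#' @param series an `imu_angle_series` or any list with `time` and `theta`.
#' @param fc_times foot-contact instants (s) on the series' (aligned) clock.
#' @return Numeric vector of angles (deg), one per foot contact.
#' @export
angles_at_fc <- function(series, fc_times) {
  inside <- fc_times >= series$time[1] & fc_times <= series$time[length(series$time)]
  out <- rep(NA_real_, length(fc_times))
  if (any(inside)) {
    out[inside] <- stats::approx(series$time, series$theta,
                                 xout = fc_times[inside], ties = "ordered")$y
  }
  if (any(!inside)) {
    warning(sprintf("%d foot contact(s) outside the angle series support; excluded",
                    sum(!inside)))
    attr(out, "excluded") <- which(!inside)
  }
  out
}

#' @export
print.imu_angle_series <- function(x, ...) {
  cat(sprintf("<imu_angle_series: %s, %s method, %d samples, range [%.1f, %.1f] deg>\n",
              x$segment, x$method, length(x$theta),
              min(x$theta), max(x$theta)))
  invisible(x)
}
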