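# Sagittal kinematics from marker trajectories: the motion-capture arm of the
# pipeline and the reference against which IMU angles are judged.
#
# Landmark conventions: knee center = midpoint of the femoral epicondyle
# markers; ankle center = midpoint of the malleoli; foot vector = calcaneus to
# second metatarsal head. Thigh = trochanter -> knee center, shank = knee
# center -> ankle center. Overstriding uses the greater trochanter and the
# *lateral* malleolus markers, and leg length is defined as the static-pose
# distance between those same two markers so the normalized value is a pure
# function of the landmarks that define it.

#' Sagittal segment angle from two marker trajectories
#'
#' For vertical-referenced segments (thigh, shank) the angle is
#' `atan2(forward component of proximal->distal, -vertical component)`:
#' zero when the segment hangs straight down, positive when the distal end is
#' ahead of the proximal end. For the horizontal-referenced foot the input is
#' the heel->toe vector and the angle is
#' `atan2(vertical component, forward component)`: zero for a flat foot,
#' positive when the toe is above the heel (rear-foot strike).
#'
#' @param proximal,distal n x 3 matrices of marker positions (m); for the foot
#'   pass heel and toe.
#' @param reference `"vertical"` (thigh/shank) or `"horizontal"` (foot).
#' @param forward unit 2D direction of progression in the horizontal plane
#'   (components along lab X and Y).
#' @return Numeric vector of angles in degrees.
#' @export
segment_angle_from_markers <- function(proximal, distal,
                                       reference = c("vertical", "horizontal"),
                                       forward = c(1, 0)) {
  reference <- match.arg(reference)
  forward <- forward / sqrt(sum(forward^2))
  v <- as.matrix(distal) - as.matrix(proximal)
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-9)) {
    stop(sprintf("zero-length segment vector at frame %d", which(len < 1e-9)[1]))
  }
  f <- v[, 1] * forward[1] + v[, 2] * forward[2]
  z <- v[, 3]
  if (reference == "vertical") {
    theta <- atan2(f, -z)
  } else {
    theta <- atan2(z, f)
  }
  theta * 180 / pi
}

interp_at <- function(time, x, at) {
  if (any(at < time[1] - 1e-9) || any(at > time[length(time)] + 1e-9)) {
    stop("requested instant outside the series support")
  }
  stats::approx(time, x, xout = at, ties = "ordered", rule = 2)$y
}

#' Overstriding from the trochanter and lateral malleolus markers
#'
#' Overstriding is the horizontal (direction-of-progression) distance between
#' the greater trochanter and the lateral malleolus at foot contact, positive
#' when the foot is ahead of the hip, normalized by leg length. Marker series
#' are linearly interpolated to each foot-contact instant.
#'
#' @param trochanter,lateral_malleolus n x 3 marker matrices (m).
#' @param time sample times of the marker series (s).
#' @param fc_times foot-contact instants (s), inside the series support.
#' @param leg_length leg length (m), > 0.
#' @param forward unit 2D progression direction.
#' @return Data frame with columns `raw` (m) and `normalized` (raw/leg_length).
#' @export
overstriding_from_markers <- function(trochanter, lateral_malleolus, time,
                                      fc_times, leg_length, forward = c(1, 0)) {
  stopifnot(leg_length > 0)
  forward <- forward / sqrt(sum(forward^2))
  d <- as.matrix(lateral_malleolus) - as.matrix(trochanter)
  horiz <- d[, 1] * forward[1] + d[, 2] * forward[2]
  raw <- interp_at(time, horiz, fc_times)
  data.frame(raw = raw, normalized = raw / leg_length)
}

#' Leg length from a static standing trial
#'
#' Mean 3D distance between the greater trochanter and the lateral malleolus
#' markers over the trial.
#'
#' @param static_trial a markers [trial_table()] of at least 0.5 s containing
#'   `trochanter_{x,y,z}` and `mall_lat_{x,y,z}` columns, or a list with
#'   n x 3 matrices `trochanter` and `lateral_malleolus`.
#' @return Leg length in meters.
#' @export
leg_length_from_static <- function(static_trial) {
  if (inherits(static_trial, "trial_table")) {
    if (diff(range(static_trial$time)) < 0.5) {
      stop("static trial must cover at least 0.5 s")
    }
    tr <- marker_xyz(static_trial, "trochanter")
    ml <- marker_xyz(static_trial, "mall_lat")
  } else {
    tr <- as.matrix(static_trial$trochanter)
    ml <- as.matrix(static_trial$lateral_malleolus)
  }
  mean(sqrt(rowSums((ml - tr)^2)))
}

#' Direction of progression from a reference marker
#'
#' Unit horizontal vector along the net displacement of a reference marker
#' (e.g. the suprasternal notch) over a window. Errors out for treadmill-like
#' data whose net displacement is below 0.3 m; callers should then use the lab
#' +X convention.
#'
#' @param marker n x 3 marker matrix (m) over the window of interest.
#' @param min_displacement minimal net horizontal displacement (m).
#' @return Unit 2D vector (components along lab X and Y).
#' @export
forward_direction <- function(marker, min_displacement = 0.3) {
  marker <- as.matrix(marker)
  d <- marker[nrow(marker), 1:2] - marker[1, 1:2]
  nrm <- sqrt(sum(d^2))
  if (nrm < min_displacement) {
    stop(sprintf(paste("net horizontal displacement %.3f m is below %.1f m;",
                       "treadmill-like data -- use the lab +X convention"),
                 nrm, min_displacement))
  }
  as.numeric(d / nrm)
}

marker_xyz <- function(trial, name) {
  cols <- paste0(name, c("_x", "_y", "_z"))
  miss <- setdiff(cols, names(trial$data))
  if (length(miss) > 0L) {
    stop("missing marker columns: ", paste(miss, collapse = ", "))
  }
  as.matrix(trial$data[cols])
}

#' Thigh, shank and foot angle series from a standard marker table
#'
#' Applies the package's landmark conventions to a markers trial and returns
#' the three sagittal angle series.
#'
#' @param trial a markers [trial_table()] with trochanter, knee_lat/knee_med,
#'   mall_lat/mall_med, heel and toe markers.
#' @param forward unit 2D progression direction.
#' @return List with `time` and numeric vectors `thigh`, `shank`, `foot` (deg).
#' @export
marker_segment_angles <- function(trial, forward = c(1, 0)) {
  troch <- marker_xyz(trial, "trochanter")
  knee <- (marker_xyz(trial, "knee_lat") + marker_xyz(trial, "knee_med")) / 2
  ankle <- (marker_xyz(trial, "mall_lat") + marker_xyz(trial, "mall_med")) / 2
  heel <- marker_xyz(trial, "heel")
  toe <- marker_xyz(trial, "toe")
  list(time = trial$time,
       thigh = segment_angle_from_markers(troch, knee, "vertical", forward),
       shank = segment_angle_from_markers(knee, ankle, "vertical", forward),
       foot = segment_angle_from_markers(heel, toe, "horizontal", forward))
}
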