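# Synthetic running-data generator with known ground truth.
#
# The generator emulates the study design end to end: participants with drawn
# anthropometry run five metronome-paced treadmill trials (stride frequencies
# 75-95 strides/min at 3 m/s, which systematically modulates overstriding)
# and one comfortable-speed overground trial with force plates on part of the
# path, after a standing pose and a calibration maneuver (hard step + forward
# / backward leg swing). The skeleton is planar (sagittal only), consistent
# with the hinge-joint assumption of the per-frame IMU calibration; marker,
# force and IMU streams are all derived from the same continuous segment-angle
# functions, so they are mutually consistent and every pipeline stage has an
# exact oracle.
#
# Timeline of every running trial (seconds from trial start):
#   [0, 1.5)    quiet standing (segments vertical, foot flat)
#   [1.5, 4.0)  calibration maneuver
#   [4.0, 6.0)  smooth ramp into the periodic gait pattern
#   6.0 ...     running; foot contact k at 6.0 + k * T
# Stride periods are rounded to the 200 Hz marker grid so that true foot
# contacts are grid instants (commanded stride frequencies are honored to
# within 0.15 strides/min); this keeps the geometric ground truth exact at
# foot contact.

GRAVITY <- 9.80665

#' Synthetic study configuration
#'
#' Defaults emulate the study conditions: 10 participants (mass 71.8 +/- 15.3
#' kg, leg length 0.89 +/- 0.04 m), five 30-s treadmill trials at 3 m/s paced
#' at 75/80/85/90/95 strides/min, and one overground trial at a comfortable
#' self-selected speed (2.9 +/- 0.27 m/s) and stride frequency (81 +/- 3.5
#' strides/min) with force plates covering pairs of consecutive strides every
#' fifth stride. Foot-contact angle targets decrease with stride frequency;
#' peak braking force is generated from a random-intercept linear model on the
#' standardized FC angles. IMU corruption: mounting offsets (free spin about
#' the joint axis, small tilt, axis relabeling), heading drift about gravity,
#' white orientation noise, low-frequency soft-tissue wobble, and a start
#' delay of 90-180 ms per sensor.
#'
#' @param n_participants number of participants.
#' @param seed integer seed; a fixed seed reproduces the study byte for byte.
#' @param leg_length_mean,leg_length_sd leg length distribution (m).
#' @param mass_mean,mass_sd body mass distribution (kg).
#' @param thigh_frac,shank_frac split of the trochanter-to-malleolus distance.
#' @param foot_length heel-to-toe marker distance (m).
#' @param tm_speed treadmill belt speed (m/s).
#' @param sf_levels treadmill metronome stride frequencies (strides/min).
#' @param strides_per_tm_trial strides per treadmill trial.
#' @param og_duration overground trial duration (s).
#' @param og_speed_mean,og_speed_sd overground speed distribution (m/s).
#' @param og_sf_mean,og_sf_sd overground stride-frequency distribution.
#' @param og_plate_every a pair of consecutive strides lands on force plates
#'   every this many strides.
#' @param og_speed_noise_sd per-stride speed multiplier noise.
#' @param og_outlier_prob,og_outlier_size probability and size of per-stride
#'   speed excursions (exercises the 5 percent speed filter).
#' @param angle_mean_sf85 FC-angle means at 85 strides/min (deg;
#'   thigh/shank/foot).
#' @param angle_slope_per_sf change of the FC-angle means per stride/min.
#' @param participant_angle_sd between-participant FC-angle offsets (deg).
#' @param stride_angle_sd stride-to-stride FC-angle noise (deg).
#' @param thigh_shank_noise_cor correlation of thigh/shank stride noise
#'   (negative: placement compensation).
#' @param swing_amp,swing_sin,swing_amp2 waveform harmonics (deg): cosine,
#'   sine and second-harmonic amplitudes of the within-stride angle curves.
#' @param fc_threshold vertical-GRF contact threshold the bumps cross exactly
#'   at the true events (N).
#' @param peak_vgrf_bw vertical GRF peak (body weights).
#' @param duty_mean,duty_participant_sd,duty_stride_sd duty-cycle model.
#' @param pbf_beta generative coefficients of the standardized-PBF model
#'   (thigh, shank, foot).
#' @param pbf_sigma_b,pbf_sigma_e participant-intercept and residual SD of the
#'   standardized-PBF model.
#' @param pbf_mean_bw,pbf_scale_bw affine map from the standardized scale to
#'   body weights.
#' @param pbf_min_bw lower clip for generated PBF (BW).
#' @param marker_rate,force_rate,imu_rate stream sampling rates (Hz).
#' @param imu_noise_sd_deg white orientation noise, per-axis SD (deg).
#' @param wobble_amp_deg,wobble_freq_hz soft-tissue wobble amplitude and
#'   frequency (sagittal-plane, segment frame).
#' @param drift_rate_deg_s heading drift rate about gravity (deg/s); each
#'   sensor gets a random sign and a 0.5-1.5x magnitude.
#' @param mount_spin_range_deg free sensor spin about the joint axis (deg,
#'   uniform half-range).
#' @param mount_tilt_sd_deg sensor tilt off the joint axis (deg, per axis SD);
#'   violates the aligned-axis assumption by this much.
#' @param delay_range IMU start delay range (s).
#' @param marker_noise_sd marker noise SD per coordinate (m).
#' @param force_noise_sd force-plate noise SD (N).
#' @param sign_flip_prob probability per sensor of quaternion sign flips in
#'   the recorded stream.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(
    n_participants = 10, seed = 1L,
    leg_length_mean = 0.89, leg_length_sd = 0.04,
    mass_mean = 71.8, mass_sd = 15.3,
    thigh_frac = 0.53, shank_frac = 0.47, foot_length = 0.24,
    tm_speed = 3.0, sf_levels = c(75, 80, 85, 90, 95),
    strides_per_tm_trial = 25,
    og_duration = 60, og_speed_mean = 2.9, og_speed_sd = 0.27,
    og_sf_mean = 81, og_sf_sd = 3.5, og_plate_every = 5,
    og_speed_noise_sd = 0.015, og_outlier_prob = 0.08, og_outlier_size = 0.09,
    angle_mean_sf85 = c(thigh = 20, shank = 6.5, foot = 12.5),
    angle_slope_per_sf = c(thigh = -0.17, shank = -0.15, foot = -0.25),
    participant_angle_sd = c(thigh = 3, shank = 2.5, foot = 4),
    stride_angle_sd = c(thigh = 0.7, shank = 0.7, foot = 0.7),
    thigh_shank_noise_cor = -0.7,
    swing_amp = c(thigh = 22, shank = 30, foot = 35),
    swing_sin = c(thigh = 6, shank = 10, foot = 12),
    swing_amp2 = c(thigh = 3, shank = 5, foot = 6),
    fc_threshold = 20, peak_vgrf_bw = 2.6,
    duty_mean = 0.34, duty_participant_sd = 0.02, duty_stride_sd = 0.005,
    pbf_beta = c(thigh = 0.35, shank = 0.35, foot = 0.15),
    pbf_sigma_b = 0.55, pbf_sigma_e = 0.15,
    pbf_mean_bw = 0.30, pbf_scale_bw = 0.12, pbf_min_bw = 0.05,
    marker_rate = 200, force_rate = 2000, imu_rate = 120,
    imu_noise_sd_deg = 2, wobble_amp_deg = 2, wobble_freq_hz = 0.8,
    drift_rate_deg_s = 0.1,
    mount_spin_range_deg = 20, mount_tilt_sd_deg = 3,
    delay_range = c(0.090, 0.180),
    marker_noise_sd = 5e-4, force_noise_sd = 1,
    sign_flip_prob = 0.5) {
  cfg <- as.list(environment())
  sds <- c(cfg$leg_length_sd, cfg$mass_sd, cfg$participant_angle_sd,
           cfg$stride_angle_sd, cfg$pbf_sigma_b, cfg$pbf_sigma_e,
           cfg$imu_noise_sd_deg, cfg$marker_noise_sd, cfg$force_noise_sd,
           cfg$og_speed_sd, cfg$og_sf_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  if (any(cfg$sf_levels <= 0)) stop("stride-frequency levels must be positive")
  stopifnot(cfg$fc_threshold > 0, cfg$n_participants >= 1)
  structure(cfg, class = "sim_config")
}

#' A fully noiseless configuration variant
#'
#' Convenience wrapper: zero marker/force/IMU noise, wobble, tilt and drift,
#' for exact-oracle checks. Other arguments pass through to [sim_config()].
#'
#' @param ... arguments forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_noiseless <- function(...) {
  sim_config(marker_noise_sd = 0, force_noise_sd = 0, imu_noise_sd_deg = 0,
             wobble_amp_deg = 0, mount_tilt_sd_deg = 0, drift_rate_deg_s = 0,
             duty_stride_sd = 0, ...)
}

# ---- waveform machinery -----------------------------------------------------

round_period <- function(sf, rate = 200) round(60 / sf * rate) / rate

smoothstep <- function(t, t0, t1) {
  u <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  u * u * (3 - 2 * u)
}

hann_pulse <- function(t, center, width) {
  u <- (t - center) / width
  ifelse(abs(u) < 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

#' Calibration-maneuver angle waveform
#'
#' Sagittal angle (deg) of one segment during the pre-trial calibration
#' maneuver: a hard step with the instrumented foot followed by a forward and
#' a backward swing of the leg, as a sum of smooth pulses on the trial
#' timeline (maneuver window 1.5-4.0 s).
#'
#' @param t times (s) on the trial clock.
#' @param segment `"thigh"`, `"shank"` or `"foot"`.
#' @return Angle in degrees, zero outside the maneuver window.
#' @export
sim_calibration_maneuver <- function(t, segment = c("thigh", "shank", "foot")) {
  segment <- match.arg(segment)
  p <- switch(segment,
    thigh = list(c(-8, 1.90, 0.5), c(30, 2.60, 0.8), c(-18, 3.30, 0.8)),
    shank = list(c(-12, 1.90, 0.5), c(40, 2.60, 0.8), c(-25, 3.30, 0.8)),
    foot  = list(c(10, 1.85, 0.4), c(45, 2.65, 0.8), c(-30, 3.35, 0.8)))
  out <- numeric(length(t))
  for (pp in p) out <- out + pp[1] * hann_pulse(t, pp[2], pp[3])
  out
}

# Build the continuous angle function of one segment for one trial: standing,
# maneuver, ramp, then the periodic stride waveform passing exactly through
# the drawn FC targets at the FC instants.
make_angle_fun <- function(segment, fc_times, fc_targets, period, cfg,
                           t_ramp0 = 4.0, t_run0 = 6.0) {
  A <- cfg$swing_amp[[segment]]
  B <- cfg$swing_sin[[segment]]
  C2 <- cfg$swing_amp2[[segment]]
  mfun <- stats::approxfun(fc_times, fc_targets - A, rule = 2)
  force(period)
  function(t) {
    cal <- sim_calibration_maneuver(t, segment)
    phase <- 2 * pi * (t - t_run0) / period
    per <- mfun(t) + A * cos(phase) + B * sin(phase) + C2 * (cos(2 * phase) - 1)
    r <- smoothstep(t, t_ramp0, t_run0)
    cal + r * per * (t >= t_ramp0)
  }
}

# Reference mean/SD of the FC angles over the treadmill design, used to place
# the generative PBF model on a standardized scale. Deterministic in config.
angle_z_refs <- function(cfg) {
  segs <- c("thigh", "shank", "foot")
  out <- lapply(segs, function(s) {
    lev <- cfg$angle_mean_sf85[[s]] +
      cfg$angle_slope_per_sf[[s]] * (cfg$sf_levels - 85)
    mu <- mean(lev)
    v_lev <- mean((lev - mu)^2)
    sd <- sqrt(v_lev + cfg$participant_angle_sd[[s]]^2 +
                 cfg$stride_angle_sd[[s]]^2)
    c(mu = mu, sd = sd)
  })
  names(out) <- segs
  out
}

# ---- mounting and orientation corruption ------------------------------------

rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  quat_normalize(q)
}

# Random sensor mounting: axis relabeling (signed permutation with det +1),
# free spin about the joint axis, small tilt. Returns the segment-from-sensor
# quaternion, the true sensor-frame joint axis, and the metadata axis (the
# basis vector the wearer assumes).
draw_mounting <- function(cfg) {
  perm <- sample(3)
  signs <- sample(c(-1, 1), 3, replace = TRUE)
  P <- matrix(0, 3, 3)
  for (i in 1:3) P[i, perm[i]] <- signs[i]
  if (det(P) < 0) {
    P[1, perm[1]] <- -P[1, perm[1]]
  }
  q_perm <- rotmat_to_quat(P)
  spin <- stats::runif(1, -cfg$mount_spin_range_deg, cfg$mount_spin_range_deg) * pi / 180
  q_spin <- quat_from_axis_angle(c(0, 1, 0), spin)
  tilt <- stats::rnorm(2, 0, cfg$mount_tilt_sd_deg) * pi / 180
  q_tilt <- quat_from_rotvec(c(tilt[1], 0, tilt[2]))
  q_mount <- quat_multiply(quat_multiply(q_spin, q_tilt), q_perm)
  axis_true <- as.numeric(quat_rotate(quat_conjugate(q_mount), c(0, 1, 0)))
  # the wearer knows which sensor axis lies along the joint axis, but not its
  # sign; downstream code must resolve the angle sign functionally
  axis_meta <- as.numeric(t(P) %*% c(0, 1, 0)) * sample(c(-1, 1), 1)
  list(q_mount = q_mount, axis_true = axis_true, axis_meta = axis_meta)
}

#' Simulate the IMU streams of one trial
#'
#' Corrupts the true planar segment rotations with mounting offsets, heading
#' drift about gravity, soft-tissue wobble, white orientation noise, a start
#' delay, and random quaternion sign flips, then samples at the IMU rate on
#' the sensor's own clock (which starts at the delay).
#'
#' @param theta_funs named list of continuous angle functions (deg of trial
#'   time) for `thigh`, `shank`, `foot`.
#' @param t_end trial end (s, trial clock).
#' @param cfg a [sim_config()].
#' @param delays optional named delays (s) per segment; drawn from
#'   `cfg$delay_range` when `NULL`.
#' @param mountings optional named list of mountings (see details) to reuse;
#'   drawn when `NULL`.
#' @return List with `imu` (named list of IMU [trial_table()]s on their own
#'   clocks), `meta` (data frame: segment, assumed axis), and `truth` (per
#'   segment: delay, drift rate, mounting, true sensor axis).
#' @export
simulate_imu_trial <- function(theta_funs, t_end, cfg, delays = NULL,
                               mountings = NULL) {
  segs <- names(theta_funs)
  out <- list(); meta <- list(); truth <- list()
  for (s in segs) {
    delay <- if (is.null(delays)) stats::runif(1, cfg$delay_range[1], cfg$delay_range[2]) else delays[[s]]
    mnt <- if (is.null(mountings)) draw_mounting(cfg) else mountings[[s]]
    drift_rate <- cfg$drift_rate_deg_s * stats::runif(1, 0.5, 1.5) *
      sample(c(-1, 1), 1)
    t_own <- seq(0, t_end - delay, by = 1 / cfg$imu_rate)
    t_true <- t_own + delay
    theta <- theta_funs[[s]](t_true) * pi / 180
    q_seg <- quat_from_axis_angle(c(0, 1, 0), -theta)
    q_drift <- quat_from_axis_angle(c(0, 0, 1), drift_rate * pi / 180 * t_true)
    wob <- cfg$wobble_amp_deg * pi / 180 *
      sin(2 * pi * cfg$wobble_freq_hz * t_true + stats::runif(1, 0, 2 * pi))
    noise <- matrix(stats::rnorm(3 * length(t_true), 0,
                                 cfg$imu_noise_sd_deg * pi / 180), ncol = 3)
    q_pert <- quat_from_rotvec(cbind(noise[, 1], wob + noise[, 2], noise[, 3]))
    q <- quat_multiply(q_drift, quat_multiply(q_seg, quat_multiply(q_pert, mnt$q_mount)))
    if (stats::runif(1) < cfg$sign_flip_prob && length(t_own) > 10L) {
      at <- sort(sample(length(t_own), sample(1:3, 1)))
      sgn <- rep(1, length(t_own))
      for (a in at) sgn[a:length(sgn)] <- -sgn[a:length(sgn)]
      q <- q * sgn
    }
    # rate channels: sagittal angular velocity mapped to the sensor frame,
    # gravity in the sensor frame, plus white noise
    theta_dot <- c(0, diff(theta)) * cfg$imu_rate
    omega_global <- cbind(0, -theta_dot, 0) * 180 / pi
    gyro <- quat_rotate(quat_conjugate(q), omega_global) +
      matrix(stats::rnorm(3 * length(t_own), 0, 1), ncol = 3)
    acc <- quat_rotate(quat_conjugate(q), cbind(0, 0, GRAVITY)) +
      matrix(stats::rnorm(3 * length(t_own), 0, 0.3), ncol = 3)
    dat <- data.frame(q_w = q[, 1], q_x = q[, 2], q_y = q[, 3], q_z = q[, 4],
                      gyro_x = gyro[, 1], gyro_y = gyro[, 2], gyro_z = gyro[, 3],
                      acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3])
    out[[s]] <- trial_table(t_own, dat, kind = "imu",
                            sample_rate = cfg$imu_rate)
    meta[[s]] <- data.frame(segment = s, axis_x = mnt$axis_meta[1],
                            axis_y = mnt$axis_meta[2], axis_z = mnt$axis_meta[3])
    truth[[s]] <- list(delay = delay, drift_rate = drift_rate, mounting = mnt)
  }
  list(imu = out, meta = do.call(rbind, meta), truth = truth)
}

#' Simulate the ground-reaction-force streams of one trial
#'
#' Vertical GRF: one smooth squared-sine bump per stance, scaled so the 20 N
#' threshold is crossed exactly at the true FC and TO instants; quiet standing
#' contributes a body-weight plateau that ramps out before running starts.
#' Anterior-posterior GRF: a braking lobe followed by a propulsive lobe per
#' stance, with the braking peak equal to the generated PBF.
#'
#' @param fc_times,to_times true stance boundaries (s, trial clock); only
#'   stances listed here produce force (overground plates cover a subset).
#' @param pbf_bw braking peak per stance (BW).
#' @param mass body mass (kg).
#' @param t_end trial end (s).
#' @param cfg a [sim_config()].
#' @param standing_until standing plateau end (s); `0` disables it.
#' @return A forces [trial_table()] at `cfg$force_rate`.
#' @export
simulate_grf_trial <- function(fc_times, to_times, pbf_bw, mass, t_end, cfg,
                               standing_until = 4.6) {
  t <- seq(0, t_end, by = 1 / cfg$force_rate)
  bw <- mass * GRAVITY
  fz <- numeric(length(t))
  fap <- numeric(length(t))
  if (standing_until > 0) {
    fz <- fz + bw * (1 - smoothstep(t, standing_until, standing_until + 0.6))
  }
  thr <- cfg$fc_threshold
  P <- cfg$peak_vgrf_bw * bw
  a <- asin(sqrt(thr / P))
  for (k in seq_along(fc_times)) {
    Dinner <- to_times[k] - fc_times[k]
    D <- Dinner / (1 - 2 * a / pi)
    ta <- fc_times[k] - D * a / pi
    sel <- t >= ta & t <= ta + D
    u <- (t[sel] - ta) / D
    fz[sel] <- fz[sel] + P * sin(pi * u)^2
    fap[sel] <- fap[sel] - pbf_bw[k] * bw * sin(2 * pi * u)
  }
  if (cfg$force_noise_sd > 0) {
    fz <- fz + stats::rnorm(length(t), 0, cfg$force_noise_sd)
    fap <- fap + stats::rnorm(length(t), 0, cfg$force_noise_sd)
  }
  fy <- stats::rnorm(length(t), 0, max(cfg$force_noise_sd, 0))
  trial_table(t, data.frame(f_x = fap, f_y = fy, f_z = fz),
              kind = "forces", sample_rate = cfg$force_rate)
}

# ---- per-trial and per-participant assembly ---------------------------------

# Marker table on the 200 Hz grid from the continuous angle functions and a
# hip path. Planar forward kinematics; medial/lateral marker pairs sit at
# +/- 0.03 m in y so their midpoints are the joint centers.
make_marker_trial <- function(theta_funs, hip_x_fun, hip_z_fun, t_end,
                              anthro, cfg) {
  t <- seq(0, t_end, by = 1 / cfg$marker_rate)
  th_t <- theta_funs$thigh(t) * pi / 180
  th_s <- theta_funs$shank(t) * pi / 180
  th_f <- theta_funs$foot(t) * pi / 180
  hx <- hip_x_fun(t); hz <- hip_z_fun(t)
  Lt <- anthro$thigh_length; Ls <- anthro$shank_length; Lf <- cfg$foot_length
  knee_x <- hx + Lt * sin(th_t); knee_z <- hz - Lt * cos(th_t)
  ank_x <- knee_x + Ls * sin(th_s); ank_z <- knee_z - Ls * cos(th_s)
  # heel offset rotates with the foot; toe = heel + foot vector
  hoff_x <- -0.04 * cos(th_f) - (-0.06) * sin(th_f)
  hoff_z <- -0.04 * sin(th_f) + (-0.06) * cos(th_f)
  heel_x <- ank_x + hoff_x; heel_z <- ank_z + hoff_z
  toe_x <- heel_x + Lf * cos(th_f); toe_z <- heel_z + Lf * sin(th_f)
  dy <- 0.03
  m <- data.frame(
    trochanter_x = hx, trochanter_y = 0, trochanter_z = hz,
    knee_lat_x = knee_x, knee_lat_y = -dy, knee_lat_z = knee_z,
    knee_med_x = knee_x, knee_med_y = dy, knee_med_z = knee_z,
    mall_lat_x = ank_x, mall_lat_y = -dy, mall_lat_z = ank_z,
    mall_med_x = ank_x, mall_med_y = dy, mall_med_z = ank_z,
    heel_x = heel_x, heel_y = -0.01, heel_z = heel_z,
    toe_x = toe_x, toe_y = 0.01, toe_z = toe_z,
    sst_x = hx, sst_y = 0, sst_z = hz + 0.45)
  if (cfg$marker_noise_sd > 0) {
    m <- m + matrix(stats::rnorm(nrow(m) * ncol(m), 0, cfg$marker_noise_sd),
                    nrow = nrow(m))
  }
  trial_table(t, m, kind = "markers", sample_rate = cfg$marker_rate)
}

simulate_trial <- function(anthro, condition, sf, speed, cfg,
                           n_strides, plate_strides = NULL) {
  period <- round_period(sf, cfg$marker_rate)
  t_run0 <- 6.0
  fc_all <- t_run0 + (0:n_strides) * period
  t_end <- fc_all[length(fc_all)] + 0.4 * period

  # FC angle targets: SF-level mean + participant offset + stride noise
  segs <- c("thigh", "shank", "foot")
  n_fc <- n_strides + 1L
  z1 <- stats::rnorm(n_fc); z2 <- stats::rnorm(n_fc)
  rho <- cfg$thigh_shank_noise_cor
  noise <- list(
    thigh = cfg$stride_angle_sd[["thigh"]] * z1,
    shank = cfg$stride_angle_sd[["shank"]] * (rho * z1 + sqrt(1 - rho^2) * z2),
    foot = cfg$stride_angle_sd[["foot"]] * stats::rnorm(n_fc))
  targets <- lapply(segs, function(s) {
    cfg$angle_mean_sf85[[s]] + cfg$angle_slope_per_sf[[s]] * (sf - 85) +
      anthro$angle_offset[[s]] + noise[[s]]
  })
  names(targets) <- segs

  theta_funs <- lapply(segs, function(s) {
    make_angle_fun(s, fc_all, targets[[s]], period, cfg, t_run0 = t_run0)
  })
  names(theta_funs) <- segs

  # duty cycle and stance bounds per contact
  duty <- cfg$duty_mean + anthro$duty_offset +
    stats::rnorm(n_fc, 0, cfg$duty_stride_sd)
  duty <- pmin(pmax(duty, 0.2), 0.45)
  to_all <- fc_all + duty * period

  # PBF per stride from the standardized generative model
  refs <- angle_z_refs(cfg)
  zmat <- vapply(segs, function(s) {
    (targets[[s]] - refs[[s]][["mu"]]) / refs[[s]][["sd"]]
  }, numeric(n_fc))
  pbf_z <- as.numeric(zmat %*% cfg$pbf_beta[segs]) + anthro$pbf_intercept +
    stats::rnorm(n_fc, 0, cfg$pbf_sigma_e)
  pbf_bw <- pmax(cfg$pbf_mean_bw + cfg$pbf_scale_bw * pbf_z, cfg$pbf_min_bw)

  # hip path
  if (condition == "OG") {
    mult <- 1 + stats::rnorm(n_fc, 0, cfg$og_speed_noise_sd)
    boost <- stats::runif(n_fc) < cfg$og_outlier_prob
    mult[boost] <- mult[boost] + sample(c(-1, 1), sum(boost), TRUE) * cfg$og_outlier_size
    mult_fun <- stats::approxfun(fc_all, mult, method = "constant", rule = 2)
    vel_fun <- function(t) smoothstep(t, 4.0, t_run0) * speed * mult_fun(t)
    grid <- seq(0, t_end, by = 1 / cfg$marker_rate)
    dt <- 1 / cfg$marker_rate
    vmid <- vel_fun(grid[-length(grid)] + dt / 2)
    xg <- c(0, cumsum(vmid) * dt)
    hip_x_fun <- stats::approxfun(grid, xg, rule = 2)
    stride_speed <- speed * mult
  } else {
    hip_x_fun <- function(t) {
      0.01 * smoothstep(t, 4.0, t_run0) * sin(2 * pi * (t - t_run0) / period)
    }
    stride_speed <- rep(speed, n_fc)
  }
  h0 <- anthro$leg_length + 0.07
  hip_z_fun <- function(t) {
    h0 + 0.03 * smoothstep(t, 4.0, t_run0) *
      sin(4 * pi * (t - t_run0) / period + 0.8)
  }

  markers <- make_marker_trial(theta_funs, hip_x_fun, hip_z_fun, t_end,
                               anthro, cfg)

  # overground force plates cover pairs of consecutive strides
  if (is.null(plate_strides)) {
    grf_idx <- seq_len(n_fc)
  } else {
    grf_idx <- sort(unique(plate_strides + 1L))  # stride k -> contact index k+1
    grf_idx <- grf_idx[grf_idx >= 1L & grf_idx <= n_fc]
  }
  forces <- simulate_grf_trial(fc_all[grf_idx], to_all[grf_idx],
                               pbf_bw[grf_idx], anthro$mass, t_end, cfg)

  imu_sim <- simulate_imu_trial(theta_funs, t_end, cfg)

  Lt <- anthro$thigh_length; Ls <- anthro$shank_length
  os_raw <- Lt * sin(targets$thigh * pi / 180) + Ls * sin(targets$shank * pi / 180)
  stride_truth <- data.frame(
    stride = seq_len(n_strides),
    fc = fc_all[-n_fc], to = to_all[-n_fc], next_fc = fc_all[-1L],
    theta_thigh_fc = targets$thigh[-n_fc],
    theta_shank_fc = targets$shank[-n_fc],
    theta_foot_fc = targets$foot[-n_fc],
    overstriding_raw = os_raw[-n_fc],
    overstriding_norm = os_raw[-n_fc] / anthro$leg_length,
    pbf = pbf_bw[-n_fc],
    stride_frequency = 60 / period,
    duty_cycle = (to_all[-n_fc] - fc_all[-n_fc]) / period,
    speed = stride_speed[-n_fc])

  list(condition = condition, sf = sf, speed = speed,
       markers = markers, forces = forces,
       imu = imu_sim$imu, imu_meta = imu_sim$meta,
       truth = list(fc_times = fc_all, to_times = to_all,
                    grf_contacts = grf_idx, strides = stride_truth,
                    theta_funs = theta_funs, imu = imu_sim$truth,
                    period = period))
}

#' Simulate one participant
#'
#' Draws anthropometry and participant-level effects, then simulates the five
#' treadmill trials, the overground trial, and a standing static trial.
#'
#' @param cfg a [sim_config()].
#' @param index participant index (1-based); seeds the participant's RNG
#'   stream together with `cfg$seed`.
#' @return List with `anthro` and a named list `trials`
#'   (`TM_SF75`...`TM_SF95`, `OG`, `static`), each trial as returned by the
#'   internal trial simulator with its `truth`.
#' @export
simulate_participant <- function(cfg, index) {
  set.seed(cfg$seed + 7919L * index)
  leg <- max(stats::rnorm(1, cfg$leg_length_mean, cfg$leg_length_sd), 0.7)
  mass <- max(stats::rnorm(1, cfg$mass_mean, cfg$mass_sd), 45)
  ts_total <- sqrt(leg^2 - 0.03^2)  # malleolus sits 0.03 m lateral
  anthro <- list(
    participant_id = sprintf("P%02d", index),
    leg_length = leg, mass = mass,
    thigh_length = cfg$thigh_frac * ts_total,
    shank_length = cfg$shank_frac * ts_total,
    foot_length = cfg$foot_length,
    angle_offset = list(
      thigh = stats::rnorm(1, 0, cfg$participant_angle_sd[["thigh"]]),
      shank = stats::rnorm(1, 0, cfg$participant_angle_sd[["shank"]]),
      foot = stats::rnorm(1, 0, cfg$participant_angle_sd[["foot"]])),
    duty_offset = stats::rnorm(1, 0, cfg$duty_participant_sd),
    pbf_intercept = stats::rnorm(1, 0, cfg$pbf_sigma_b),
    og_speed = max(stats::rnorm(1, cfg$og_speed_mean, cfg$og_speed_sd), 1.5),
    og_sf = max(stats::rnorm(1, cfg$og_sf_mean, cfg$og_sf_sd), 60))

  trials <- list()
  for (sf in cfg$sf_levels) {
    trials[[sprintf("TM_SF%d", sf)]] <- simulate_trial(
      anthro, sprintf("TM_SF%d", sf), sf, cfg$tm_speed, cfg,
      n_strides = cfg$strides_per_tm_trial)
  }
  og_period <- round_period(anthro$og_sf, cfg$marker_rate)
  n_og <- max(floor((cfg$og_duration - 6.0) / og_period) - 1L, 4L)
  plate <- seq(1L, n_og - 1L, by = cfg$og_plate_every)
  plate <- sort(unique(c(plate, plate + 1L)))
  trials$OG <- simulate_trial(anthro, "OG", anthro$og_sf, anthro$og_speed,
                              cfg, n_strides = n_og, plate_strides = plate)

  # static standing trial: 2 s, all segments vertical / foot flat
  static_funs <- list(thigh = function(t) 0 * t, shank = function(t) 0 * t,
                      foot = function(t) 0 * t)
  trials$static <- list(
    condition = "static",
    markers = make_marker_trial(static_funs, function(t) 0 * t,
                                function(t) 0 * t + anthro$leg_length + 0.07,
                                2.0, anthro, cfg))

  list(anthro = anthro, trials = trials)
}

#' Simulate a complete synthetic study
#'
#' @param cfg a [sim_config()].
#' @return A `sim_study`: list with `config`, `participants` (list from
#'   [simulate_participant()]), and `anthro` (data frame of participant
#'   anthropometry).
#' @export
simulate_study <- function(cfg = sim_config()) {
  participants <- lapply(seq_len(cfg$n_participants), function(i) {
    simulate_participant(cfg, i)
  })
  anthro <- do.call(rbind, lapply(participants, function(p) {
    a <- p$anthro
    data.frame(participant_id = a$participant_id, mass = a$mass,
               leg_length = a$leg_length, thigh_length = a$thigh_length,
               shank_length = a$shank_length, foot_length = a$foot_length)
  }))
  structure(list(config = cfg, participants = participants, anthro = anthro),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study: %d participants, %d trials each (seed %d)>\n",
              length(x$participants),
              length(x$participants[[1]]$trials), x$config$seed))
  invisible(x)
}

#' Simulate a stride-level dataset from the random-intercept model
#'
#' Direct generator at the statistics scale (no signal simulation):
#' `y = X beta + alpha_i + e` with standard-normal predictors, for parameter
#' recovery and coverage studies of the mixed-model fitter.
#'
#' @param n_groups number of participants.
#' @param n_per_group strides per participant.
#' @param beta fixed-effect coefficients.
#' @param sigma_b random-intercept SD.
#' @param sigma_e residual SD.
#' @return Data frame with `participant_id`, predictors `x1..xp`, response
#'   `y`, and attributes `alpha` (true intercepts).
#' @export
simulate_lmm_dataset <- function(n_groups = 10, n_per_group = 75,
                                 beta = c(0.6, 0.6, 0.05),
                                 sigma_b = 1, sigma_e = 0.3) {
  p <- length(beta)
  n <- n_groups * n_per_group
  X <- matrix(stats::rnorm(n * p), ncol = p)
  g <- rep(seq_len(n_groups), each = n_per_group)
  alpha <- stats::rnorm(n_groups, 0, sigma_b)
  y <- as.numeric(X %*% beta) + alpha[g] + stats::rnorm(n, 0, sigma_e)
  d <- data.frame(participant_id = sprintf("P%02d", g), X, y = y)
  names(d)[2:(p + 1)] <- paste0("x", seq_len(p))
  attr(d, "alpha") <- alpha
  d
}

#' Write a simulated study to a directory of CSV files
#'
#' Layout: `participants.csv` at the root; one sub-directory per participant
#' and trial holding `markers.csv`, `forces.csv`, `imu_<segment>.csv` and
#' `imu_meta.csv` (the assumed sensor-frame joint axis per segment). Ground
#' truth is not written: the files contain exactly what a laboratory session
#' would yield.
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$anthro, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  for (p in study$participants) {
    for (nm in names(p$trials)) {
      tr <- p$trials[[nm]]
      td <- file.path(dir, p$anthro$participant_id, nm)
      dir.create(td, showWarnings = FALSE, recursive = TRUE)
      write_trial(tr$markers, file.path(td, "markers.csv"))
      if (!is.null(tr$forces)) write_trial(tr$forces, file.path(td, "forces.csv"))
      if (!is.null(tr$imu)) {
        for (s in names(tr$imu)) {
          write_trial(tr$imu[[s]], file.path(td, paste0("imu_", s, ".csv")))
        }
        utils::write.csv(tr$imu_meta, file.path(td, "imu_meta.csv"),
                         row.names = FALSE)
      }
    }
  }
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir study directory.
#' @return A `sim_study`-shaped list (without ground truth or config).
#' @export
read_study <- function(dir) {
  anthro <- utils::read.csv(file.path(dir, "participants.csv"))
  participants <- lapply(anthro$participant_id, function(pid) {
    pdir <- file.path(dir, pid)
    trials <- list()
    for (nm in list.dirs(pdir, recursive = FALSE, full.names = FALSE)) {
      td <- file.path(pdir, nm)
      tr <- list(condition = nm)
      tr$markers <- read_trial(file.path(td, "markers.csv"), "markers")
      fp <- file.path(td, "forces.csv")
      if (file.exists(fp)) tr$forces <- read_trial(fp, "forces")
      imufiles <- list.files(td, pattern = "^imu_(thigh|shank|foot)\\.csv$")
      if (length(imufiles) > 0L) {
        tr$imu <- lapply(imufiles, function(f) read_trial(file.path(td, f), "imu"))
        names(tr$imu) <- sub("^imu_(.*)\\.csv$", "\\1", imufiles)
        tr$imu_meta <- utils::read.csv(file.path(td, "imu_meta.csv"))
      }
      trials[[nm]] <- tr
    }
    a <- as.list(anthro[anthro$participant_id == pid, ])
    list(anthro = a, trials = trials)
  })
  structure(list(config = NULL, participants = participants, anthro = anthro),
            class = "sim_study")
}
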