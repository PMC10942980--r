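# Small simulation configurations shared across test files.

small_cfg <- function(seed = 7, ...) {
  sim_config(n_participants = 2, strides_per_tm_trial = 18,
             og_duration = 30, seed = seed, ...)
}

small_noiseless_cfg <- function(seed = 7, n_participants = 1,
                                strides_per_tm_trial = 10,
                                og_duration = 25, ...) {
  sim_config_noiseless(n_participants = n_participants,
                       strides_per_tm_trial = strides_per_tm_trial,
                       og_duration = og_duration, seed = seed, ...)
}

# Planar truth quaternions: rotation by -theta (deg) about the global y axis,
# optionally left-composed with a heading rotation about global z.
planar_quats <- function(theta_deg, drift_deg = 0) {
  q_seg <- quat_from_axis_angle(c(0, 1, 0), -theta_deg * pi / 180)
  if (all(drift_deg == 0)) return(q_seg)
  q_drift <- quat_from_axis_angle(c(0, 0, 1), drift_deg * pi / 180)
  quat_multiply(q_drift, q_seg)
}

# Wrap quaternions (plus zero gyro channels so standing checks pass) into an
# IMU trial table.
imu_trial_from_quats <- function(time, q) {
  z <- numeric(length(time))
  trial_table(time, data.frame(q_w = q[, 1], q_x = q[, 2], q_y = q[, 3],
                               q_z = q[, 4], gyro_x = z, gyro_y = z,
                               gyro_z = z, acc_x = z, acc_y = z,
                               acc_z = z + 9.80665),
              kind = "imu")
}
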