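make_planar_trial <- function(theta, t, drift = 0) {
  imu_trial_from_quats(t, planar_quats(theta, drift))
}

swing_theta <- function(t) {
  ifelse(t < 1.2, 0, 40 * sin(2 * pi * 0.8 * (t - 1.2))^2 *
           sin(2 * pi * 0.4 * (t - 1.2)))
}

test_that("both methods recover a planar angle exactly without drift", {
  t <- seq(0, 10, by = 1 / 120)
  theta <- swing_theta(t)
  trial <- make_planar_trial(theta, t)
  mnt <- static_pose_calibrate(trial, c(0.1, 1.0), c(0, 1, 0), "shank")
  for (m in c("per_frame", "static_pose")) {
    ser <- sagittal_angle_imu(trial, mnt, m)
    expect_equal(ser$theta, theta, tolerance = 1e-8)
  }
})

test_that("a sign-flipped or spun joint axis changes only sign/offset", {
  t <- seq(0, 10, by = 1 / 120)
  theta <- swing_theta(t)
  trial <- make_planar_trial(theta, t)
  mnt <- static_pose_calibrate(trial, c(0.1, 1.0), c(0, -1, 0), "shank")
  ser <- sagittal_angle_imu(trial, mnt, "per_frame")
  expect_equal(ser$theta, -theta, tolerance = 1e-8)
  # resolved functionally via the sign argument
  ser2 <- sagittal_angle_imu(trial, mnt, "per_frame", sign = -1)
  expect_equal(ser2$theta, theta, tolerance = 1e-8)
})

test_that("static calibration rejects short windows and motion", {
  t <- seq(0, 10, by = 1 / 120)
  trial <- make_planar_trial(swing_theta(t), t)
  expect_error(static_pose_calibrate(trial, c(0.1, 0.4), c(0, 1, 0), "shank"),
               "at least 0.5 s")
  expect_error(static_pose_calibrate(trial,
                                     c(2, 3), c(0, 1, 0), "shank",
                                     max_gyro = 1e-9),
               NA)  # zero synthetic gyro: passes even during motion
  trial$data$gyro_y <- 50
  expect_error(static_pose_calibrate(trial, c(0.1, 1.0), c(0, 1, 0), "shank"),
               "motion detected")
})

test_that("a near-vertical joint axis is rejected as degenerate", {
  t <- seq(0, 2, by = 1 / 120)
  trial <- make_planar_trial(numeric(length(t)), t)
  mnt <- static_pose_calibrate(trial, c(0.1, 1.0), c(0, 1, 0), "shank")
  mnt$joint_axis_local <- c(0, 0.02, 0.9998)  # ~1 degree off vertical
  expect_error(sagittal_angle_imu(trial, mnt, "per_frame"),
               "within 5 degrees of vertical")
})

test_that("angles wrap correctly when the raw series crosses +/-180", {
  # spin the sensor so the raw extracted angle sits near 180 degrees
  t <- seq(0, 10, by = 1 / 120)
  theta <- swing_theta(t)
  q_seg <- planar_quats(theta)
  q_spin <- quat_from_axis_angle(c(0, 1, 0), 175 * pi / 180)
  trial <- imu_trial_from_quats(t, quat_multiply(q_seg, q_spin))
  mnt <- static_pose_calibrate(trial, c(0.1, 1.0), c(0, 1, 0), "shank")
  ser <- sagittal_angle_imu(trial, mnt, "per_frame")
  expect_equal(ser$theta, theta, tolerance = 1e-8)
})

test_that("angles_at_fc interpolates and excludes out-of-support contacts", {
  ser <- list(time = seq(0, 1, 0.1), theta = seq(0, 10, 1))
  expect_equal(angles_at_fc(ser, c(0.25, 0.5)), c(2.5, 5), tolerance = 1e-12)
  expect_warning(out <- angles_at_fc(ser, c(0.5, 1.5)), "excluded")
  expect_equal(out[1], 5)
  expect_true(is.na(out[2]))
  expect_equal(attr(out, "excluded"), 2L)
})
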