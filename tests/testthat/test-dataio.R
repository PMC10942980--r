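test_that("trial tables round-trip through CSV", {
  t <- seq(0, 1, by = 0.005)
  tr <- trial_table(t, data.frame(f_x = rnorm(length(t)),
                                  f_y = rnorm(length(t)),
                                  f_z = rnorm(length(t))), kind = "forces")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)
  back <- read_trial(path, "forces")
  expect_equal(back$time, tr$time)
  expect_equal(back$data, tr$data, tolerance = 1e-12)
  expect_equal(back$sample_rate, 200, tolerance = 1e-9)
})

test_that("non-uniform sampling is rejected with the offending index", {
  t <- seq(0, 1, by = 0.01)
  t[51] <- t[51] + 0.004
  expect_error(trial_table(t, data.frame(f_x = 0, f_y = 0, f_z = seq_along(t)),
                           kind = "forces"),
               "non-uniform sampling at index")
})

test_that("mandatory columns are enforced and quaternions renormalized", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = seq(0, 1, 0.01), f_x = 0),
                   path, row.names = FALSE)
  expect_error(read_trial(path, "forces"), "missing mandatory columns")

  t <- seq(0, 1, by = 1 / 120)
  q <- quat_from_axis_angle(c(0, 1, 0), t) * 3.7  # deliberately unnormalized
  utils::write.csv(data.frame(time_s = t, q_w = q[, 1], q_x = q[, 2],
                              q_y = q[, 3], q_z = q[, 4]),
                   path, row.names = FALSE)
  imu <- read_trial(path, "imu")
  nrm <- sqrt(rowSums(as.matrix(imu$data[c("q_w", "q_x", "q_y", "q_z")])^2))
  expect_equal(nrm, rep(1, length(t)), tolerance = 1e-12)
})

test_that("NA gaps are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = seq(0, 1, 0.01), f_x = 0, f_y = 0,
                              f_z = c(NA, rep(1, 100))), path,
                   row.names = FALSE)
  expect_error(read_trial(path, "forces"), "gaps are not supported")
})

test_that("stride records round-trip with a stable column order", {
  rec <- data.frame(participant_id = "P01", condition = "TM_SF85",
                    stride = 1:2, fc = c(6, 6.7),
                    theta_thigh_fc = c(20, 21), theta_shank_fc = c(6, 7),
                    theta_foot_fc = c(12, 13), theta_thigh_imu_fc = c(19, 22),
                    theta_shank_imu_fc = c(5, 8), theta_foot_imu_fc = c(11, 14),
                    overstriding_raw = c(0.19, 0.20),
                    overstriding_norm = c(0.21, 0.22), pbf = c(0.3, 0.31),
                    stride_frequency = c(85, 85), duty_cycle = c(0.34, 0.33),
                    speed = c(NA, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stride_records(rec[, sample(ncol(rec))], path)  # scrambled order
  back <- read_stride_records(path)
  expect_equal(names(back)[1:4], c("participant_id", "condition", "stride", "fc"))
  expect_equal(back$overstriding_raw, rec$overstriding_raw)
})

test_that("pipeline_config validates and reads YAML overrides", {
  expect_error(pipeline_config(fc_threshold = -5), "fc_threshold")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("marker_cutoff: 8", "tm_keep_last: 10"), path)
  cfg <- read_config_yaml(path)
  expect_equal(cfg$marker_cutoff, 8)
  expect_equal(cfg$tm_keep_last, 10)
  expect_equal(cfg$force_cutoff, 50)
  writeLines("not_a_field: 1", path)
  expect_error(read_config_yaml(path), "unknown config fields")
})
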