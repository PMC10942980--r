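test_that("the same seed reproduces the study exactly", {
  a <- simulate_participant(small_cfg(seed = 5), 1)
  b <- simulate_participant(small_cfg(seed = 5), 1)
  expect_identical(a$trials$TM_SF85$markers$data, b$trials$TM_SF85$markers$data)
  expect_identical(a$trials$OG$imu$shank$data, b$trials$OG$imu$shank$data)
  c2 <- simulate_participant(small_cfg(seed = 6), 1)
  expect_false(identical(a$trials$TM_SF85$markers$data,
                         c2$trials$TM_SF85$markers$data))
})

test_that("the study has the prescribed design", {
  cfg <- small_cfg(seed = 9)
  st <- simulate_study(cfg)
  expect_s3_class(st, "sim_study")
  expect_length(st$participants, 2)
  p <- st$participants[[1]]
  expect_named(p$trials, c(sprintf("TM_SF%d", cfg$sf_levels), "OG", "static"),
               ignore.order = TRUE)
  tm <- p$trials$TM_SF90
  expect_equal(nrow(tm$truth$strides), cfg$strides_per_tm_trial)
  expect_equal(tm$truth$strides$stride_frequency[1], 90, tolerance = 0.005)
  expect_equal(tm$markers$sample_rate, 200)
  expect_equal(tm$forces$sample_rate, 2000)
  expect_equal(tm$imu$thigh$sample_rate, 120)
  # overground plates cover pairs of strides; stride truth exists for all
  og <- p$trials$OG
  expect_gt(length(og$truth$grf_contacts), 4)
})

test_that("ground-truth overstriding satisfies the geometric identity", {
  cfg <- small_noiseless_cfg()
  p <- simulate_participant(cfg, 1)
  tr <- p$trials$TM_SF85$truth$strides
  lt <- p$anthro$thigh_length
  ls <- p$anthro$shank_length
  os <- lt * sin(tr$theta_thigh_fc * pi / 180) +
    ls * sin(tr$theta_shank_fc * pi / 180)
  expect_equal(tr$overstriding_raw, os, tolerance = 1e-12)
  expect_equal(tr$overstriding_norm, os / p$anthro$leg_length,
               tolerance = 1e-12)
})

test_that("GRF crosses the threshold exactly at the true events", {
  cfg <- small_noiseless_cfg()
  fc <- c(1.0, 1.8)
  to <- c(1.25, 2.05)
  forces <- simulate_grf_trial(fc, to, pbf_bw = c(0.2, 0.3), mass = 70,
                               t_end = 3, cfg = cfg, standing_until = 0)
  f <- function(tt) {
    stats::approx(forces$time, forces$data$f_z, xout = tt)$y
  }
  for (ev in c(fc, to)) {
    expect_equal(f(ev), cfg$fc_threshold, tolerance = 0.02)
  }
  # braking peak equals the requested PBF in BW
  bw <- 70 * 9.80665
  sel <- forces$time >= fc[1] & forces$time <= to[1]
  expect_equal(max(-forces$data$f_x[sel]) / bw, 0.2, tolerance = 1e-3)
})

test_that("IMU truth is consistent: delayed clock, drift, mounting", {
  cfg <- small_noiseless_cfg(seed = 13)
  p <- simulate_participant(cfg, 1)
  tr <- p$trials$TM_SF85
  s <- tr$truth$imu$shank
  expect_gte(s$delay, cfg$delay_range[1])
  expect_lte(s$delay, cfg$delay_range[2])
  expect_equal(s$drift_rate, 0)  # noiseless config
  # metadata axis is the true axis up to sign (no tilt in noiseless config)
  meta <- tr$imu_meta
  am <- as.numeric(meta[meta$segment == "shank", c("axis_x", "axis_y", "axis_z")])
  expect_equal(abs(am), abs(s$mounting$axis_true), tolerance = 1e-9)
  # the recorded quaternions reproduce the true angle through the extraction
  mnt <- static_pose_calibrate(tr$imu$shank, c(0.1, 1.0),
                               s$mounting$axis_true, "shank")
  ser <- sagittal_angle_imu(tr$imu$shank, mnt, "per_frame")
  truth <- tr$truth$theta_funs$shank(ser$time + s$delay)
  expect_lt(sqrt(mean((ser$theta - truth)^2)), 1e-6)
})

test_that("simulate_lmm_dataset has the generative structure", {
  set.seed(21)
  d <- simulate_lmm_dataset(10, 75, beta = c(0.6, 0.6, 0.05),
                            sigma_b = 1, sigma_e = 0.3)
  expect_equal(dim(d), c(750, 5))
  expect_equal(length(unique(d$participant_id)), 10)
  expect_length(attr(d, "alpha"), 10)
})

test_that("a study round-trips through the CSV directory layout", {
  cfg <- small_noiseless_cfg(seed = 3, strides_per_tm_trial = 6,
                             og_duration = 18)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "participants.csv")))
  back <- read_study(dir)
  expect_equal(back$anthro$mass, st$anthro$mass, tolerance = 1e-9)
  orig <- st$participants[[1]]$trials$TM_SF85
  got <- back$participants[[1]]$trials$TM_SF85
  expect_equal(got$markers$data$trochanter_x, orig$markers$data$trochanter_x,
               tolerance = 1e-9)
  expect_equal(got$imu$foot$time, orig$imu$foot$time, tolerance = 1e-9)
  expect_null(got$truth)
})

test_that("sim_config validates inputs", {
  expect_error(sim_config(mass_sd = -1), "standard deviations")
  expect_error(sim_config(sf_levels = c(80, -5)), "positive")
})
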