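test_that("segment angles follow the sign conventions", {
  # thigh hanging straight down: 0; distal end 30 degrees ahead: +30
  prox <- matrix(c(0, 0, 1), 1)
  for (ang in c(-20, 0, 30)) {
    dist <- prox + 0.4 * c(sin(ang * pi / 180), 0, -cos(ang * pi / 180))
    expect_equal(segment_angle_from_markers(prox, matrix(dist, 1), "vertical"),
                 ang, tolerance = 1e-10)
  }
  # foot: heel -> toe flat is 0; toe above heel positive (rear-foot strike)
  heel <- matrix(c(0, 0, 0.05), 1)
  for (ang in c(-10, 0, 15)) {
    toe <- heel + 0.24 * c(cos(ang * pi / 180), 0, sin(ang * pi / 180))
    expect_equal(segment_angle_from_markers(heel, matrix(toe, 1), "horizontal"),
                 ang, tolerance = 1e-10)
  }
})

test_that("angles respect an oblique direction of progression", {
  fwd <- c(1, 1) / sqrt(2)
  prox <- matrix(c(0, 0, 1), 1)
  dist <- prox + 0.4 * c(sin(0.3) * fwd[1], sin(0.3) * fwd[2], -cos(0.3))
  expect_equal(segment_angle_from_markers(prox, matrix(dist, 1), "vertical",
                                          forward = fwd),
               0.3 * 180 / pi, tolerance = 1e-10)
})

test_that("zero-length segments are rejected with the frame index", {
  m <- matrix(c(0, 0, 1), 2, 3, byrow = TRUE)
  expect_error(segment_angle_from_markers(m, m, "vertical"),
               "zero-length segment vector at frame 1")
})

test_that("overstriding is the horizontal trochanter-to-malleolus distance", {
  t <- seq(0, 1, by = 0.005)
  troch <- cbind(0.1 * t, 0, 0.9)
  mall <- cbind(0.1 * t + 0.15 + 0.01 * sin(2 * pi * t), 0.03, 0.08)
  os <- overstriding_from_markers(troch, mall, t, fc_times = c(0.25, 0.5),
                                  leg_length = 0.9)
  expect_equal(os$raw, 0.15 + 0.01 * sin(2 * pi * c(0.25, 0.5)),
               tolerance = 1e-9)
  expect_equal(os$normalized, os$raw / 0.9, tolerance = 1e-12)
  expect_error(overstriding_from_markers(troch, mall, t, 2, 0.9),
               "outside the series support")
})

test_that("leg length comes from the static trochanter-malleolus distance", {
  t <- seq(0, 1, by = 0.005)
  static <- list(trochanter = cbind(0, 0, 0.97),
                 lateral_malleolus = cbind(0, 0.03, 0.08))
  expect_equal(leg_length_from_static(static),
               sqrt(0.89^2 + 0.03^2), tolerance = 1e-12)
})

test_that("forward_direction needs net displacement (treadmill errors out)", {
  walk <- cbind(seq(0, 5, length.out = 100), seq(0, 1, length.out = 100), 1)
  fwd <- forward_direction(walk)
  expect_equal(fwd, c(5, 1) / sqrt(26), tolerance = 1e-12)
  tm <- cbind(0.01 * sin(seq(0, 10, length.out = 100)), 0, 1)
  expect_error(forward_direction(tm), "treadmill-like")
})

test_that("marker_segment_angles applies the landmark conventions", {
  cfg <- small_noiseless_cfg()
  p <- simulate_participant(cfg, 1)
  tr <- p$trials$TM_SF85
  ang <- marker_segment_angles(tr$markers)
  truth <- tr$truth$theta_funs
  for (s in c("thigh", "shank", "foot")) {
    expect_equal(ang[[s]], truth[[s]](ang$time), tolerance = 1e-8)
  }
})
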