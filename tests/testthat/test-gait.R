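test_that("threshold crossings are found with sub-sample precision", {
  rate <- 2000
  t <- seq(0, 2, by = 1 / rate)
  # linear ramps crossing 20 N at exactly t = 0.5 (up) and t = 1.25 (down)
  fz <- pmax(0, pmin(1, (t - 0.4) * 5, (1.4 - t) * 4)) * 200 - 0
  fz <- ifelse(t < 0.4 | t > 1.4, 0, fz)
  fc_true <- 0.4 + 0.1 * (20 / 200) / 0.5 * 5  # solve 200*(t-0.4)*5... use direct
  ev <- detect_foot_contacts(t, fz, threshold = 20)
  expect_length(ev$fc_times, 1)
  # 200*(t-0.4)*5 = 20 -> t = 0.42 ; 200*(1.4-t)*4 = 20 -> t = 1.375
  expect_equal(ev$fc_times, 0.42, tolerance = 1e-9)
  expect_equal(ev$to_times, 1.375, tolerance = 1e-9)
})

test_that("edge-touching stances and chatter are handled", {
  t <- seq(0, 3, by = 5e-4)
  fz <- numeric(length(t))
  fz[t < 0.3] <- 100                      # touches the start: dropped
  fz[t > 1 & t < 1.3] <- 100              # stance A
  fz[t > 1.31 & t < 1.6] <- 100           # chatter dip of 10 ms: merged into A
  fz[t > 2 & t < 2.03] <- 100             # too-short stance: dropped
  ev <- expect_silent(detect_foot_contacts(t, fz, threshold = 20,
                                           min_stance = 0.1,
                                           min_flight = 0.05))
  expect_length(ev$fc_times, 1)
  expect_lt(abs(ev$fc_times - 1.0), 1e-3)
  expect_lt(abs(ev$to_times - 1.6), 1e-3)
})

test_that("no crossings warns and returns empty events", {
  expect_warning(ev <- detect_foot_contacts(seq(0, 1, 0.001),
                                            rep(5, 1001), threshold = 20),
                 "no complete threshold crossings")
  expect_length(ev$fc_times, 0)
})

test_that("peak braking force is the posterior peak in body weights", {
  t <- seq(0, 1, by = 5e-4)
  f_ap <- -150 * sin(2 * pi * (t - 0.2) / 0.3) * (t >= 0.2 & t <= 0.5)
  pbf <- peak_braking_force(t, f_ap, fc = 0.2, to = 0.5, body_weight = 700)
  expect_equal(pbf, 150 / 700, tolerance = 1e-3)
  expect_warning(zero <- peak_braking_force(t, abs(f_ap), 0.2, 0.5, 700),
                 "no posterior force")
  expect_equal(zero, 0)
  expect_error(peak_braking_force(t, f_ap, -0.5, 0.5, 700), "support")
})

test_that("stride metrics skip non-adjacent contacts", {
  ev <- structure(list(fc_times = c(1, 1.7, 2.4, 6.0, 6.7),
                       to_times = c(1.24, 1.94, 2.64, 6.24, 6.94)),
                  class = "stride_events")
  sm <- stride_frequency_and_duty(ev, max_stride_time = 1.6)
  expect_equal(nrow(sm), 3)  # 1->1.7, 1.7->2.4, 6.0->6.7; the 2.4->6.0 gap is out
  expect_equal(sm$stride_frequency, rep(60 / 0.7, 3), tolerance = 1e-9)
  expect_equal(sm$duty_cycle, rep(0.24 / 0.7, 3), tolerance = 1e-9)
})

test_that("select_strides keeps last TM strides and the OG speed band", {
  rec <- data.frame(
    participant_id = "P01",
    condition = rep(c("TM_SF85", "OG"), c(20, 10)),
    fc = c(1:20, 1:10), stride = c(1:20, 1:10),
    speed = c(rep(NA, 20), c(3, 3.02, 2.98, 3.6, 3.01, 2.4, 2.99, 3.05,
                             3.0, 2.97)))
  out <- select_strides(rec, tm_keep_last = 15, og_speed_band = 0.05)
  tm <- out[out$condition == "TM_SF85", ]
  expect_equal(tm$stride, 6:20)
  og <- out[out$condition == "OG", ]
  expect_false(any(og$speed %in% c(3.6, 2.4)))
  expect_equal(nrow(og), 8)
  expect_warning(select_strides(rec[rec$stride <= 5 |
                                      rec$condition == "OG", ],
                                tm_keep_last = 15),
                 "keeping all")
})
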