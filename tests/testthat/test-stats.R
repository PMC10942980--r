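test_that("REML fit matches the EM-REML oracle on the printed fixture", {
  d <- lmm_fixture()
  fit <- fit_stride_lmm(d, "y", c("x1", "x2"))
  oracle <- em_reml(d$y, cbind(1, d$x1, d$x2), d$participant_id)
  expect_equal(unname(coef(fit)), oracle$beta[2:3], tolerance = 1e-6)
  expect_equal(fit$sigma2_b, oracle$s2b, tolerance = 1e-6)
  expect_equal(fit$sigma2_e, oracle$s2e, tolerance = 1e-6)
})

test_that("single-group data reduces to OLS", {
  d <- lmm_fixture()
  d1 <- d[d$participant_id == "A", ]
  expect_warning(fit <- fit_stride_lmm(d1, "y", c("x1", "x2")),
                 "single group")
  ols <- stats::lm(y ~ x1 + x2, data = d1)
  expect_equal(unname(coef(fit)), unname(stats::coef(ols)[2:3]),
               tolerance = 1e-8)
  expect_equal(fit$sigma2_b, 0)
  expect_equal(fit$icc, 0)
})

test_that("Wald inference and ICC/R2 identities hold", {
  d <- lmm_fixture()
  fit <- fit_stride_lmm(d, "y", c("x1", "x2"))
  b <- fit$beta
  expect_equal(b$ci_low, b$estimate - stats::qnorm(0.975) * b$se,
               tolerance = 1e-12)
  expect_equal(b$p_value, 2 * stats::pnorm(-abs(b$estimate / b$se)),
               tolerance = 1e-12)
  expect_equal(fit$icc, fit$sigma2_b / (fit$sigma2_b + fit$sigma2_e),
               tolerance = 1e-12)
  r2 <- variance_explained(fit)
  tot <- fit$sigma2_f + fit$sigma2_b + fit$sigma2_e
  expect_equal(unname(r2), c(fit$sigma2_f / tot,
                             (fit$sigma2_f + fit$sigma2_b) / tot),
               tolerance = 1e-12)
  expect_gte(fit$r2_conditional, fit$r2_marginal)
})

test_that("S3 methods behave", {
  d <- lmm_fixture()
  fit <- fit_stride_lmm(d, "y", c("x1", "x2"))
  expect_named(coef(fit), c("x1", "x2"))
  expect_length(predict(fit), nrow(d))
  expect_output(print(fit), "Random-intercept LMM")
  expect_output(print(summary(fit)), "Variance components")
  pr <- predict(fit, newdata = d)
  expect_equal(pr, predict(fit), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("zscore_columns standardizes and flags zero variance", {
  d <- data.frame(a = c(1, 2, 3, 4), b = rep(2, 4))
  z <- zscore_columns(d, "a")
  expect_equal(mean(z$data$a), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$data$a), 1, tolerance = 1e-12)
  expect_equal(z$data$a * z$scale[["a"]] + z$center[["a"]], d$a,
               tolerance = 1e-12)
  expect_error(zscore_columns(d, c("a", "b")), "zero-variance column")
})

test_that("rmse_fc pools per segment and respects the TM prefix", {
  rec <- data.frame(condition = c("TM_SF75", "TM_SF95", "OG"),
                    theta_thigh_fc = c(10, 12, 14),
                    theta_thigh_imu_fc = c(11, 10, 14),
                    theta_shank_fc = 0, theta_shank_imu_fc = 3,
                    theta_foot_fc = 0, theta_foot_imu_fc = 0)
  r <- rmse_fc(rec, "TM")
  expect_equal(r$rmse_deg[r$segment == "thigh"], sqrt(mean(c(1, 4))),
               tolerance = 1e-12)
  expect_equal(r$n, rep(2, 3))
  r_og <- rmse_fc(rec, "OG")
  expect_equal(r_og$rmse_deg[r_og$segment == "thigh"], 0)
})

test_that("run_model_menu fits the eight-model grid", {
  set.seed(99)
  # build stride-record-shaped data directly (fast): two conditions
  n <- 400
  rec <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:4), each = n / 4),
    condition = rep(c("TM_SF85", "OG"), n / 2),
    theta_thigh_fc = rnorm(n, 20, 3), theta_shank_fc = rnorm(n, 6, 2),
    theta_foot_fc = rnorm(n, 12, 4))
  rec$theta_thigh_imu_fc <- rec$theta_thigh_fc + rnorm(n, 0, 2)
  rec$theta_shank_imu_fc <- rec$theta_shank_fc + rnorm(n, 0, 2)
  rec$theta_foot_imu_fc <- rec$theta_foot_fc + rnorm(n, 0, 2)
  rec$overstriding_norm <- 0.5 * sin(rec$theta_thigh_fc * pi / 180) +
    0.4 * sin(rec$theta_shank_fc * pi / 180) + rnorm(n, 0, 0.002)
  rec$pbf <- 0.3 + 0.01 * as.numeric(scale(rec$theta_thigh_fc)) +
    rnorm(n, 0, 0.02)
  rec$duty_cycle <- rnorm(n, 0.34, 0.01)
  # fabricated records have no participant effects: boundary fits expected
  menu <- suppressWarnings(run_model_menu(rec, reduced = TRUE))
  labels <- c("os_tm_mocap", "pbf_tm_mocap", "os_tm_imu", "pbf_tm_imu",
              "os_og_mocap", "pbf_og_mocap", "os_og_imu", "pbf_og_imu")
  expect_true(all(labels %in% names(menu)))
  expect_true(all(c("pbf_tm_imu_thigh_shank", "pbf_tm_imu_shank",
                    "pbf_tm_imu_duty") %in% names(menu)))
  expect_s3_class(menu$os_tm_mocap, "stride_lmm")
  expect_output(print(menu), "ICC")
})
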