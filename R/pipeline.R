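# End-to-end pipeline: raw trial streams -> stride records -> mixed models.
#
# Per running trial: low-pass filter markers (10 Hz) and forces (50 Hz,
# zero-phase); establish the direction of progression (net suprasternal
# displacement overground, lab +X on the treadmill); compute marker segment
# angles and overstriding; detect foot contacts from the vertical GRF;
# calibrate each IMU on the standing window, extract its sagittal angle
# (static-pose method on the treadmill, per-frame gravity/joint-axis
# redefinition overground), resolve the angle sign and the sensor start delay
# by cross-correlation against the motion-capture angle of the same segment
# over the calibration maneuver, and align. One record per stride carries the
# paired mocap/IMU FC angles, overstriding, PBF, stride frequency, duty cycle
# and speed. Records are then filtered to the analyzed subset (last 15
# treadmill strides; overground strides within 5 percent of the median speed)
# and fed to the random-intercept model menu.
#
# Every stage is wrapped so failures identify the stage and the trial.

with_stage <- function(stage, context, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed (%s): %s",
                 stage, context, conditionMessage(e)), call. = FALSE)
  })
}

#' Process one running trial into stride records
#'
#' Runs the full single-trial chain (filtering, progression direction, marker
#' kinematics, event detection, IMU calibration + synchronization + angle
#' extraction, per-stride metrics). See the module description for the stage
#' order.
#'
#' @param trial list with `condition`, `markers`, `forces`, `imu` (named list
#'   of IMU [trial_table()]s) and `imu_meta` (data frame with `segment`,
#'   `axis_x`, `axis_y`, `axis_z`: the assumed sensor-frame joint axis, sign
#'   ambiguity allowed).
#' @param participant_id participant label.
#' @param mass body mass (kg).
#' @param leg_length leg length (m) from the static trial.
#' @param config a [pipeline_config()].
#' @return List with `records` (one row per stride) and `lags` (per-segment
#'   synchronization table: `lag`, `peak_correlation`, `sign`).
#' @export
process_trial <- function(trial, participant_id, mass, leg_length,
                          config = pipeline_config()) {
  ctx <- paste0(participant_id, "/", trial$condition)
  is_og <- !startsWith(trial$condition, "TM")

  markers_f <- with_stage("filter", ctx,
    filter_trial(trial$markers, config$marker_cutoff, config$filter_order))
  forces_f <- with_stage("filter", ctx,
    filter_trial(trial$forces, config$force_cutoff, config$filter_order,
                 channels = c("f_x", "f_y", "f_z")))

  forward <- with_stage("forward_direction", ctx, {
    if (is_og) {
      forward_direction(marker_xyz(markers_f, "sst"))
    } else {
      c(1, 0)  # treadmill: no net displacement, lab +X convention
    }
  })

  angles <- with_stage("marker_kinematics", ctx,
    marker_segment_angles(markers_f, forward))

  events <- with_stage("events", ctx,
    detect_foot_contacts(forces_f$time, forces_f$data$f_z,
                         threshold = config$fc_threshold,
                         min_stance = config$min_stance,
                         min_flight = config$min_flight))
  strides <- with_stage("events", ctx, stride_frequency_and_duty(events))
  if (nrow(strides) == 0L) {
    stop(sprintf("pipeline stage 'events' failed (%s): no complete strides detected",
                 ctx), call. = FALSE)
  }

  os <- with_stage("overstriding", ctx,
    overstriding_from_markers(marker_xyz(markers_f, "trochanter"),
                              marker_xyz(markers_f, "mall_lat"),
                              markers_f$time, strides$fc, leg_length, forward))

  f_ap <- forces_f$data$f_x * forward[1] + forces_f$data$f_y * forward[2]
  bw <- mass * GRAVITY
  pbf <- with_stage("braking_force", ctx, vapply(seq_len(nrow(strides)),
    function(k) peak_braking_force(forces_f$time, f_ap, strides$fc[k],
                                   strides$to[k], bw),
    numeric(1)))

  if (is.null(trial[["imu"]]) || length(trial[["imu"]]) == 0L) {
    stop(sprintf("pipeline stage 'calibrate' failed (%s): no IMU streams in trial",
                 ctx), call. = FALSE)
  }
  method <- if (is_og) config$imu_method_og else config$imu_method_tm
  imu_fc <- list()
  lag_rows <- list()
  for (s in names(trial[["imu"]])) {
    meta <- trial[["imu_meta"]][trial[["imu_meta"]]$segment == s, , drop = FALSE]
    if (nrow(meta) != 1L) {
      stop(sprintf("pipeline stage 'calibrate' failed (%s): no axis metadata for segment %s",
                   ctx, s), call. = FALSE)
    }
    axis <- as.numeric(meta[1, c("axis_x", "axis_y", "axis_z")])
    mounting <- with_stage("calibrate", ctx,
      static_pose_calibrate(trial[["imu"]][[s]], window = c(0.1, 1.0), axis,
                            segment = s))
    series <- with_stage("imu_angle", ctx,
      sagittal_angle_imu(trial[["imu"]][[s]], mounting, method = method,
                         reference = if (s == "foot") "horizontal" else "vertical"))
    sync <- with_stage("synchronize", ctx, {
      sel_r <- angles$time <= config$sync_window
      sel_m <- series$time <= config$sync_window
      ref <- resample_linear(angles$time[sel_r], angles[[s]][sel_r],
                             config$analysis_rate)
      mov <- resample_linear(series$time[sel_m], series$theta[sel_m],
                             config$analysis_rate)
      estimate_lag(ref$x, mov$x, config$analysis_rate, config$sync_max_lag)
    })
    sgn <- if (sync$peak_correlation < 0) -1 else 1
    series$theta <- sgn * series$theta
    series <- apply_lag(series, sync$lag)
    imu_fc[[s]] <- with_stage("imu_angle", ctx,
      angles_at_fc(series, strides$fc))
    lag_rows[[s]] <- data.frame(
      participant_id = participant_id, condition = trial$condition,
      segment = s, lag = sync$lag,
      peak_correlation = abs(sync$peak_correlation), sign = sgn)
  }

  speed <- if (is_og) {
    sst <- marker_xyz(markers_f, "sst")
    along <- sst[, 1] * forward[1] + sst[, 2] * forward[2]
    pos <- stats::approx(markers_f$time, along,
                         xout = c(strides$fc, strides$next_fc),
                         ties = "ordered")$y
    n <- nrow(strides)
    (pos[(n + 1):(2 * n)] - pos[1:n]) / (strides$next_fc - strides$fc)
  } else {
    rep(NA_real_, nrow(strides))
  }

  records <- data.frame(
    participant_id = participant_id, condition = trial$condition,
    stride = seq_len(nrow(strides)), fc = strides$fc,
    theta_thigh_fc = interp_at(angles$time, angles$thigh, strides$fc),
    theta_shank_fc = interp_at(angles$time, angles$shank, strides$fc),
    theta_foot_fc = interp_at(angles$time, angles$foot, strides$fc),
    theta_thigh_imu_fc = as.numeric(imu_fc$thigh),
    theta_shank_imu_fc = as.numeric(imu_fc$shank),
    theta_foot_imu_fc = as.numeric(imu_fc$foot),
    overstriding_raw = os$raw, overstriding_norm = os$normalized,
    pbf = pbf,
    stride_frequency = strides$stride_frequency,
    duty_cycle = strides$duty_cycle,
    speed = speed)
  list(records = records, lags = do.call(rbind, lag_rows))
}

#' Run the complete analysis pipeline on a study
#'
#' Processes every running trial of every participant (see [process_trial()]),
#' filters the stride records to the analyzed subset with [select_strides()],
#' computes the per-segment mocap-vs-IMU FC-angle RMSE, and fits the
#' eight-model random-intercept menu with [run_model_menu()].
#'
#' @param study a `sim_study` from [simulate_study()], or a path to a study
#'   directory written by [write_study()].
#' @param config a [pipeline_config()].
#' @param reduced_models also fit the reduced-predictor model variants.
#' @return A `pipeline_result`: list with `records` (analyzed strides),
#'   `records_all` (before selection), `lags`, `rmse`, `models`, `config`.
#' @export
run_pipeline <- function(study, config = pipeline_config(),
                         reduced_models = FALSE) {
  if (is.character(study)) study <- read_study(study)
  all_records <- list(); all_lags <- list()
  for (p in study$participants) {
    pid <- p$anthro$participant_id
    mass <- p$anthro$mass
    leg_length <- with_stage("leg_length", pid, {
      if (!is.null(p$trials$static)) {
        st <- filter_trial(p$trials$static$markers, config$marker_cutoff,
                           config$filter_order)
        leg_length_from_static(st)
      } else if (!is.null(p$anthro$leg_length)) {
        p$anthro$leg_length
      } else {
        stop("no static trial and no leg_length metadata")
      }
    })
    for (nm in names(p$trials)) {
      if (identical(p$trials[[nm]]$condition, "static")) next
      res <- process_trial(p$trials[[nm]], pid, mass, leg_length, config)
      all_records[[paste(pid, nm)]] <- res$records
      all_lags[[paste(pid, nm)]] <- res$lags
    }
  }
  records_all <- do.call(rbind, all_records)
  rownames(records_all) <- NULL
  records <- with_stage("select_strides", "all",
    select_strides(records_all, config$tm_keep_last, config$og_speed_band))

  conds <- unique(ifelse(startsWith(as.character(records$condition), "TM"),
                         "TM", "OG"))
  rmse <- do.call(rbind, lapply(conds, function(cc) {
    cbind(condition = cc, rmse_fc(records, cc))
  }))
  models <- with_stage("models", "all",
    run_model_menu(records, reduced = reduced_models))
  structure(list(records = records, records_all = records_all,
                 lags = do.call(rbind, all_lags), rmse = rmse,
                 models = models, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d analyzed strides (%d before selection), %d participants>\n",
              nrow(x$records), nrow(x$records_all),
              length(unique(x$records$participant_id))))
  cat("FC-angle RMSE (mocap vs IMU), deg:\n")
  print(transform(x$rmse, rmse_deg = round(rmse_deg, 2)), row.names = FALSE)
  cat(sprintf("models: %s\n", paste(names(x$models), collapse = ", ")))
  invisible(x)
}

#' Summarize stride records per condition
#'
#' Per-condition means and SDs of the headline quantities (overstriding in cm,
#' PBF in BW, stride frequency, duty cycle), pooled over participants.
#'
#' @param records stride-record data frame.
#' @return Data frame, one row per condition.
#' @export
summarize_records <- function(records) {
  pieces <- split(records, records$condition)
  out <- lapply(pieces, function(d) {
    data.frame(condition = d$condition[1], n_strides = nrow(d),
               os_cm_mean = mean(d$overstriding_raw) * 100,
               os_cm_sd = stats::sd(d$overstriding_raw) * 100,
               pbf_bw_mean = mean(d$pbf), pbf_bw_sd = stats::sd(d$pbf),
               sf_mean = mean(d$stride_frequency),
               duty_mean = mean(d$duty_cycle))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
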