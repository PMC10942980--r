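# File formats and configuration. CSV is the interchange format: the pipeline
# is self-contained and instrument-agnostic. Column layouts:
#   markers.csv : time_s, <marker>_x, <marker>_y, <marker>_z   (m, lab frame)
#   forces.csv  : time_s, f_x (anterior +), f_y (left +), f_z (vertical +)  (N)
#   imu_<seg>.csv : time_s, q_w, q_x, q_y, q_z, gyro_x..z (deg/s), acc_x..z (m/s^2)
# Time is in seconds with an arbitrary per-stream origin; streams are unaligned
# until synchronization because the IMUs start recording after motion capture.

#' Construct a trial table
#'
#' A trial table holds one uniformly sampled multi-channel series: a time
#' vector, a data frame of channels, and the sampling rate.
#'
#' @param time numeric vector of sample times (s), strictly increasing and
#'   uniform.
#' @param data data frame of channel values, one row per sample.
#' @param kind one of `"markers"`, `"forces"`, `"imu"`.
#' @param sample_rate sampling rate in Hz; inferred from `time` when `NULL`.
#' @return An object of class `trial_table`.
#' @export
trial_table <- function(time, data, kind = c("markers", "forces", "imu"),
                        sample_rate = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(time), nrow(data) == length(time))
  if (is.null(sample_rate)) sample_rate <- infer_sample_rate(time)
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  structure(list(time = as.numeric(time), data = as.data.frame(data),
                 kind = kind, sample_rate = sample_rate),
            class = "trial_table")
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("<trial_table: %s, %d samples @ %g Hz, %d channels>\n",
              x$kind, length(x$time), x$sample_rate, ncol(x$data)))
  cat("  channels:", paste(utils::head(names(x$data), 12), collapse = ", "),
      if (ncol(x$data) > 12) "..." else "", "\n")
  invisible(x)
}

infer_sample_rate <- function(time, rel_tol = 1e-6) {
  if (length(time) < 2L) stop("need at least 2 samples to infer a sample rate")
  dt <- diff(time)
  step <- stats::median(dt)
  bad <- which(abs(dt - step) > rel_tol * max(abs(step), 1e-12))
  if (length(bad) > 0L) {
    stop(sprintf("non-uniform sampling at index %d (step %.6g s, expected %.6g s)",
                 bad[1] + 1L, dt[bad[1]], step))
  }
  1 / step
}

mandatory_columns <- function(kind) {
  switch(kind,
    markers = "time_s",
    forces  = c("time_s", "f_x", "f_y", "f_z"),
    imu     = c("time_s", "q_w", "q_x", "q_y", "q_z"))
}

#' Read a trial CSV
#'
#' Reads one of the pipeline's CSV layouts, checks time-axis uniformity,
#' infers the sampling rate, and renormalizes quaternion columns to unit norm.
#' Sample values are otherwise never altered.
#'
#' @param path path to a CSV file with a header row; the first column is time
#'   in seconds.
#' @param kind `"markers"`, `"forces"` or `"imu"`.
#' @return A [trial_table()].
#' @export
read_trial <- function(path, kind = c("markers", "forces", "imu")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- mandatory_columns(kind)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("missing mandatory columns in %s: %s", path,
                 paste(miss, collapse = ", ")))
  }
  time <- df[["time_s"]]
  rate <- infer_sample_rate(time)
  dat <- df[setdiff(names(df), "time_s")]
  if (kind == "imu") {
    q <- quat_normalize(as.matrix(dat[c("q_w", "q_x", "q_y", "q_z")]))
    dat[c("q_w", "q_x", "q_y", "q_z")] <- as.data.frame(q)
  }
  if (anyNA(dat)) stop("NA values in ", path, "; gaps are not supported")
  trial_table(time, dat, kind = kind, sample_rate = rate)
}

#' Write a trial table to CSV
#' @param trial a [trial_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  df <- cbind(time_s = trial$time, trial$data)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

stride_record_columns <- c(
  "participant_id", "condition", "stride", "fc",
  "theta_thigh_fc", "theta_shank_fc", "theta_foot_fc",
  "theta_thigh_imu_fc", "theta_shank_imu_fc", "theta_foot_imu_fc",
  "overstriding_raw", "overstriding_norm", "pbf",
  "stride_frequency", "duty_cycle", "speed")

#' Write stride records to CSV
#'
#' One row per stride with a stable column order; round-trips losslessly
#' through [read_stride_records()]. An empty record set writes a header-only
#' file.
#'
#' @param records data frame of stride records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stride_records <- function(records, path) {
  records <- as.data.frame(records)
  keep <- intersect(stride_record_columns, names(records))
  extra <- setdiff(names(records), keep)
  records <- records[c(keep, extra)]
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read stride records written by [write_stride_records()]
#' @param path CSV path.
#' @return Data frame of stride records.
#' @export
read_stride_records <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Holds the processing constants of the pipeline. Defaults follow standard
#' practice for running analyses: 10 Hz marker / 50 Hz force low-pass cutoffs,
#' a 20 N vertical-force threshold for foot contact, the last 15 strides of
#' each treadmill trial, and a 5 percent speed band for overground strides.
#'
#' @param marker_cutoff marker low-pass cutoff (Hz).
#' @param force_cutoff force low-pass cutoff (Hz).
#' @param filter_order Butterworth order (applied bidirectionally).
#' @param fc_threshold vertical-GRF foot-contact threshold (N).
#' @param tm_keep_last number of final treadmill strides retained per trial.
#' @param og_speed_band overground speed filter half-width, as a fraction of
#'   the median stride speed.
#' @param analysis_rate common analysis rate (Hz) used for synchronization.
#' @param sync_max_lag largest lag searched during synchronization (s). Each
#'   IMU is synchronized against the motion-capture angle series of its own
#'   segment, because every sensor has its own start delay.
#' @param sync_window end (s) of the window used for synchronization. The
#'   window must cover the calibration maneuver (the unique, non-periodic
#'   anchor) and benefits from also covering the first running strides, whose
#'   sharper features tighten the correlation peak; this is unambiguous
#'   because the stride period exceeds twice `sync_max_lag`.
#' @param imu_method_tm,imu_method_og IMU angle method per condition:
#'   `"static_pose"` or `"per_frame"`.
#' @param min_stance,min_flight event debouncing windows (s).
#' @param seed integer seed used by stages that draw random numbers.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(marker_cutoff = 10, force_cutoff = 50,
                            filter_order = 4, fc_threshold = 20,
                            tm_keep_last = 15, og_speed_band = 0.05,
                            analysis_rate = 200, sync_max_lag = 0.25,
                            sync_window = 12.0,
                            imu_method_tm = "static_pose",
                            imu_method_og = "per_frame",
                            min_stance = 0.1, min_flight = 0.05,
                            seed = 1L) {
  cfg <- list(marker_cutoff = marker_cutoff, force_cutoff = force_cutoff,
              filter_order = filter_order, fc_threshold = fc_threshold,
              tm_keep_last = tm_keep_last, og_speed_band = og_speed_band,
              analysis_rate = analysis_rate, sync_max_lag = sync_max_lag,
              sync_window = sync_window,
              imu_method_tm = match.arg(imu_method_tm, c("static_pose", "per_frame")),
              imu_method_og = match.arg(imu_method_og, c("static_pose", "per_frame")),
              min_stance = min_stance, min_flight = min_flight,
              seed = as.integer(seed))
  if (cfg$fc_threshold <= 0) stop("fc_threshold must be > 0")
  if (cfg$marker_cutoff <= 0 || cfg$force_cutoff <= 0)
    stop("filter cutoffs must be > 0")
  stopifnot(cfg$sync_max_lag > 0, cfg$sync_window > 2 * cfg$sync_max_lag)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override [pipeline_config()] defaults; unknown
#' fields are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}
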