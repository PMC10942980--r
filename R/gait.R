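# Gait events and force-side metrics. Foot contact (FC) is the instant the
# vertical GRF rises through a 20 N threshold, toe-off (TO) the instant it
# falls back through it; crossing times are refined to sub-sample precision by
# linear interpolation on the native force grid. Debouncing windows reject
# threshold chatter from noise.

#' Detect foot contacts and toe-offs from the vertical GRF
#'
#' @param time sample times (s) at the native force rate.
#' @param fz vertical GRF (N, positive up).
#' @param threshold contact threshold (N), default 20.
#' @param min_stance shortest accepted stance duration (s).
#' @param min_flight shortest accepted flight duration (s); shorter
#'   sub-threshold dips are treated as chatter and merged into the stance.
#' @return A `stride_events` list with `fc_times` and `to_times` (each stance
#'   is `[fc_times[k], to_times[k]]`). Empty with a warning when no crossings
#'   are found.
#' @export
detect_foot_contacts <- function(time, fz, threshold = 20,
                                 min_stance = 0.1, min_flight = 0.05) {
  stopifnot(threshold > 0)
  above <- fz >= threshold
  n <- length(fz)
  cross_time <- function(i) {
    # linear interpolation of the crossing instant between samples i and i+1
    f0 <- fz[i]; f1 <- fz[i + 1L]
    time[i] + (threshold - f0) / (f1 - f0) * (time[i + 1L] - time[i])
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  st <- which(r$values)
  # a run touching either edge of the record has no complete FC/TO pair
  st <- st[starts[st] > 1L & ends[st] < n]
  if (length(st) == 0L) {
    warning("no complete threshold crossings found; returning empty events")
    return(structure(list(fc_times = numeric(0), to_times = numeric(0)),
                     class = "stride_events"))
  }
  fc <- vapply(starts[st] - 1L, cross_time, numeric(1))
  to <- vapply(ends[st], cross_time, numeric(1))
  # merge stances separated by sub-min_flight dips (threshold chatter)
  if (length(fc) > 1L) {
    keep_fc <- fc[1]; keep_to <- numeric(0); cur_to <- to[1]
    for (k in seq(2L, length(fc))) {
      if (fc[k] - cur_to < min_flight) {
        cur_to <- to[k]
      } else {
        keep_to <- c(keep_to, cur_to)
        keep_fc <- c(keep_fc, fc[k])
        cur_to <- to[k]
      }
    }
    keep_to <- c(keep_to, cur_to)
    fc <- keep_fc; to <- keep_to
  }
  keep <- (to - fc) >= min_stance
  structure(list(fc_times = fc[keep], to_times = to[keep]),
            class = "stride_events")
}

#' @export
print.stride_events <- function(x, ...) {
  cat(sprintf("<stride_events: %d stances", length(x$fc_times)))
  if (length(x$fc_times) > 0) {
    cat(sprintf(", t = [%.2f, %.2f] s", x$fc_times[1],
                x$to_times[length(x$to_times)]))
  }
  cat(">\n")
  invisible(x)
}

#' Peak braking force over one stance
#'
#' The peak of the posterior-directed (negative-forward) component of the
#' anterior-posterior GRF during stance, normalized by body weight and
#' returned as a positive number in BW. An all-propulsive stance returns 0
#' with a warning.
#'
#' @param time force sample times (s).
#' @param f_ap anterior-posterior GRF (N, anterior positive).
#' @param fc,to stance boundaries (s).
#' @param body_weight body weight (N), > 0.
#' @return Peak braking force in BW.
#' @export
peak_braking_force <- function(time, f_ap, fc, to, body_weight) {
  stopifnot(body_weight > 0)
  if (fc < time[1] || to > time[length(time)]) {
    stop("stance outside the force series support")
  }
  sel <- time >= fc & time <= to
  braking <- -f_ap[sel]
  pk <- max(braking)
  if (pk <= 0) {
    warning("no posterior force during stance; peak braking force set to 0")
    return(0)
  }
  pk / body_weight
}

#' Per-stride stride frequency and duty cycle
#'
#' Stride `k` spans `[FC_k, FC_{k+1})`. `SF_k = 60 / (FC_{k+1} - FC_k)`
#' strides/min and `duty_k = (TO_k - FC_k) / (FC_{k+1} - FC_k)`. Non-adjacent
#' contacts (gaps longer than `max_stride_time`, e.g. between overground
#' force-plate passes) do not form strides.
#'
#' @param events a `stride_events` from [detect_foot_contacts()].
#' @param max_stride_time longest accepted stride duration (s).
#' @return Data frame with `fc`, `to`, `next_fc`, `stride_frequency`,
#'   `duty_cycle`; zero rows when fewer than two adjacent contacts exist.
#' @export
stride_frequency_and_duty <- function(events, max_stride_time = 1.6) {
  fc <- events$fc_times; to <- events$to_times
  if (length(fc) < 2L) {
    return(data.frame(fc = numeric(0), to = numeric(0), next_fc = numeric(0),
                      stride_frequency = numeric(0), duty_cycle = numeric(0)))
  }
  dt <- diff(fc)
  k <- which(dt <= max_stride_time)
  data.frame(fc = fc[k], to = to[k], next_fc = fc[k + 1L],
             stride_frequency = 60 / dt[k],
             duty_cycle = (to[k] - fc[k]) / dt[k])
}

#' Filter stride records to the analyzed subset
#'
#' Treadmill trials keep the last `tm_keep_last` strides of each
#' participant-condition trial (all strides, with a warning, when fewer
#' exist). Overground trials keep strides whose speed is within
#' `og_speed_band` of the median stride speed.
#'
#' @param records stride-record data frame with `participant_id`, `condition`
#'   and (for overground rows) `speed` columns.
#' @param tm_keep_last number of final treadmill strides kept.
#' @param og_speed_band overground half-band as a fraction of the median
#'   speed.
#' @param og_label condition label identifying overground rows.
#' @return Filtered data frame.
#' @export
select_strides <- function(records, tm_keep_last = 15, og_speed_band = 0.05,
                           og_label = "OG") {
  pieces <- split(records, list(records$participant_id, records$condition),
                  drop = TRUE)
  out <- lapply(pieces, function(d) {
    if (d$condition[1] == og_label) {
      med <- stats::median(d$speed)
      d[abs(d$speed - med) <= og_speed_band * med, , drop = FALSE]
    } else {
      if (nrow(d) < tm_keep_last) {
        warning(sprintf("only %d strides for %s/%s; keeping all",
                        nrow(d), d$participant_id[1], d$condition[1]))
        d
      } else {
        utils::tail(d, tm_keep_last)
      }
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$participant_id, res$condition, res$fc), , drop = FALSE]
}
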