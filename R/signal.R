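# Filtering, resampling and cross-correlation synchronization. Zero phase is
# non-negotiable here: foot-contact instants anchor every metric, and a causal
# filter would shift them.

#' Bidirectional (zero-phase) Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward, giving
#' zero phase and a squared magnitude response. The series is extended at both
#' ends by odd reflection before filtering to suppress edge transients.
#'
#' @param x numeric series.
#' @param sample_rate sampling rate (Hz).
#' @param cutoff cutoff frequency (Hz); must be below the Nyquist rate.
#' @param order filter order for each pass (default 4).
#' @return Filtered series, same length as `x`.
#' @export
filter_lowpass <- function(x, sample_rate, cutoff, order = 4) {
  if (cutoff >= sample_rate / 2) {
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 cutoff, sample_rate / 2))
  }
  n <- length(x)
  padlen <- min(9L * order, n - 1L)
  if (n < 3L * padlen) stop("series too short for stable zero-phase filtering")
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  # odd reflection: 2*x[1] - x[(padlen+1):2], keeps level and slope continuous
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  ext <- c(pre, x, post)
  fwd <- signal::filter(bf, ext)
  bwd <- rev(signal::filter(bf, rev(fwd)))
  as.numeric(bwd[(padlen + 1L):(padlen + n)])
}

#' Low-pass filter every channel of a trial table
#'
#' @param trial a [trial_table()].
#' @param cutoff cutoff frequency (Hz).
#' @param order Butterworth order per pass.
#' @param channels channel names to filter (default: all numeric channels).
#' @return A `trial_table` with filtered channels.
#' @export
filter_trial <- function(trial, cutoff, order = 4, channels = NULL) {
  if (is.null(channels)) {
    channels <- names(trial$data)[vapply(trial$data, is.numeric, logical(1))]
  }
  for (ch in channels) {
    trial$data[[ch]] <- filter_lowpass(trial$data[[ch]], trial$sample_rate,
                                       cutoff, order)
  }
  trial
}

#' Resample a series by linear interpolation
#'
#' @param time sample times (s), strictly increasing.
#' @param x values at `time`.
#' @param target_rate new sampling rate (Hz).
#' @return List with components `time` and `x` on the new uniform grid, which
#'   starts at `time[1]` and covers the original support.
#' @export
resample_linear <- function(time, x, target_rate) {
  if (length(x) == 0L) stop("cannot resample an empty series")
  if (target_rate <= 0) stop("target_rate must be > 0")
  new_time <- seq(time[1], time[length(time)], by = 1 / target_rate)
  list(time = new_time,
       x = stats::approx(time, x, xout = new_time, ties = "ordered")$y)
}

#' Estimate the delay between two synchronized-rate series
#'
#' Maximizes the normalized cross-correlation magnitude between a reference
#' series and a delayed copy over integer lags in `[-max_lag, +max_lag]`, then
#' refines the peak to sub-sample precision by parabolic interpolation. A
#' positive lag means the moving stream starts later than the reference (its
#' samples correspond to later reference times).
#'
#' The signed peak correlation is reported: a value near -1 flags a
#' sign-convention mismatch between the two streams that the caller should
#' resolve before alignment.
#'
#' @param reference,moving numeric series sampled at the same rate over the
#'   same nominal window.
#' @param sample_rate common sampling rate (Hz).
#' @param max_lag largest delay magnitude searched (s).
#' @return List with `lag` (s) and `peak_correlation` (in `[-1, 1]`).
#' @export
estimate_lag <- function(reference, moving, sample_rate, max_lag) {
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0) {
    stop("no correlation structure: flat (zero-variance) input")
  }
  L <- floor(max_lag * sample_rate)
  n <- min(length(reference), length(moving))
  if (n <= 2L * L + 2L) stop("overlap too short for the requested max_lag")
  lags <- (-L):L
  cc <- vapply(lags, function(k) {
    # moving shifted by +k samples corresponds to reference k samples later
    if (k >= 0) {
      a <- reference[(k + 1L):n]; b <- moving[1L:(n - k)]
    } else {
      a <- reference[1L:(n + k)]; b <- moving[(-k + 1L):n]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }, numeric(1))
  i <- which.max(abs(cc))
  s <- sign(cc[i])
  lag <- lags[i] / sample_rate
  # parabolic refinement on |cc| around the integer peak
  if (i > 1L && i < length(cc)) {
    y0 <- abs(cc[i - 1L]); y1 <- abs(cc[i]); y2 <- abs(cc[i + 1L])
    den <- y0 - 2 * y1 + y2
    if (abs(den) > 1e-12) {
      delta <- 0.5 * (y0 - y2) / den
      delta <- max(min(delta, 0.5), -0.5)
      lag <- (lags[i] + delta) / sample_rate
    }
  }
  list(lag = lag, peak_correlation = cc[i] * 1)
}

#' Shift a stream's time axis by an estimated delay
#'
#' Adds `lag` to the stream's time stamps so that its events line up with the
#' reference clock. Works on a [trial_table()] or on any list with a `time`
#' component (e.g. an IMU angle series).
#'
#' @param x a `trial_table` or a list with a numeric `time` component.
#' @param lag delay in seconds (positive = stream started later).
#' @return `x` with shifted times.
#' @export
apply_lag <- function(x, lag) {
  dur <- diff(range(x$time))
  if (abs(lag) >= dur) stop("|lag| must be smaller than the series duration")
  x$time <- x$time + lag
  x
}
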