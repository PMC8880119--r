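# Shear-wave tensiometry signal chain: band-pass filtering of the raw
# two-channel tap-accelerometer recording, tap-event detection by template
# cross-correlation, inter-channel travel-time estimation with cosine
# subsample peak interpolation, and conversion to a quality-flagged wave
# speed series (speed = accelerometer spacing / travel time).

#' Two-channel accelerometer recording
#'
#' @param ch1,ch2 equal-length numeric acceleration sample vectors; channel 1
#'   is proximal (nearer the tapper), channel 2 distal.
#' @param fs sample rate in Hz (> 0).
#' @param start_time time of the first sample in s.
#' @return an `accel_recording` object.
#' @export
accel_recording <- function(ch1, ch2, fs, start_time = 0) {
  stopifnot(length(ch1) == length(ch2), fs > 0)
  structure(list(ch1 = as.numeric(ch1), ch2 = as.numeric(ch2),
                 fs = fs, start_time = start_time),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording: %d samples/channel @ %.5g Hz, %.3f s>\n",
              length(x$ch1), x$fs, length(x$ch1) / x$fs))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass of the given overall order to both
#' channels, forward and backward (zero phase, preserving tap timing).
#' Defaults match the tensiometry analysis band of 150-1500 Hz, fourth
#' order.
#'
#' @param rec an [accel_recording()].
#' @param low,high cutoff frequencies in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param order overall filter order (even; `order = 4` designs a
#'   two-section band-pass).
#' @return the filtered [accel_recording()].
#' @export
bandpass_filter <- function(rec, low = 150, high = 1500, order = 4) {
  stopifnot(inherits(rec, "accel_recording"), order %% 2 == 0, order >= 2)
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("cutoffs must satisfy 0 < low < high < fs/2 (fs/2 = ", nyq, " Hz)")
  }
  bf <- signal::butter(order / 2, c(low, high) / nyq, type = "pass")
  rec$ch1 <- as.numeric(signal::filtfilt(bf, rec$ch1))
  rec$ch2 <- as.numeric(signal::filtfilt(bf, rec$ch2))
  rec
}

# Sliding-window energy of x for windows of length L (vector of length
# length(x) - L + 1, window starting at each index).
sliding_energy <- function(x, L) {
  cs <- cumsum(c(0, x^2))
  cs[(L + 1):length(cs)] - cs[1:(length(cs) - L)]
}

#' Detect tap events by template cross-correlation
#'
#' Cross-correlates a representative tap waveform with channel 1 and takes
#' the times of peak normalized correlation as tap events. With
#' `template = "auto"` the representative tap is the highest-energy 2 ms
#' segment of channel 1 (for an isolated burst this window locks onto the
#' burst support, so detected times land on tap onsets). An energy contrast
#' guard rejects recordings with no impulsive content (e.g. pure noise)
#' before any correlation threshold is applied.
#'
#' @param rec a band-passed [accel_recording()].
#' @param template numeric template samples, or `"auto"`.
#' @param min_spacing minimum separation between taps in s; of two closer
#'   candidates the higher-correlation one is kept.
#' @param corr_floor minimum normalized correlation for a tap.
#' @param template_dur auto-template duration in s.
#' @return numeric vector of tap times in s (recording clock); empty, with a
#'   warning, when no taps are found.
#' @export
detect_taps <- function(rec, template = "auto", min_spacing = 0.005,
                        corr_floor = 0.6, template_dur = 0.002) {
  stopifnot(inherits(rec, "accel_recording"))
  x <- rec$ch1
  L <- max(8L, round(template_dur * rec$fs))
  if (length(x) < 2L * L) {
    warning("recording shorter than two template lengths; no taps detected")
    return(numeric(0))
  }
  en <- sliding_energy(x, L)
  if (identical(template, "auto")) {
    # impulsive content check: the best window must clearly beat the bulk
    if (max(en) < 20 * (stats::median(en) + .Machine$double.eps)) {
      warning("no impulsive tap content found; no taps detected")
      return(numeric(0))
    }
    j <- which.max(en)
    template <- x[j:(j + L - 1L)]
  }
  L <- length(template)
  template <- template - mean(template)
  tn <- sqrt(sum(template^2))
  if (tn <= .Machine$double.eps) {
    warning("flat template; no taps detected")
    return(numeric(0))
  }
  n <- length(x)
  nfft <- stats::nextn(n + L, 2L)
  fx <- fft(c(x, rep(0, nfft - n)))
  ft <- fft(c(template, rep(0, nfft - L)))
  cc <- Re(fft(fx * Conj(ft), inverse = TRUE))[seq_len(n - L + 1L)] / nfft
  ncc <- cc / (tn * sqrt(pmax(sliding_energy(x, L), .Machine$double.eps)))
  peaks <- pick_peaks(ncc, height = corr_floor,
                      min_sep = round(min_spacing * rec$fs))
  if (!length(peaks)) {
    warning("no taps above the correlation floor")
    return(numeric(0))
  }
  rec$start_time + (peaks - 1L) / rec$fs
}

#' Inter-channel travel time for one tap
#'
#' Estimates the delay of channel 2 relative to channel 1 over the analysis
#' window following a tap: the integer-lag argmax of the normalized
#' cross-correlation is refined by fitting a cosine through the peak and its
#' two neighbours ([cosine_peak_offset()]), giving subsample resolution.
#'
#' @param ch1_window,ch2_window equal-length sample windows (typically the
#'   first 4 ms after the tap).
#' @param fs sample rate in Hz.
#' @param max_lag maximum absolute lag searched, in samples.
#' @return list with `delay_s`, `delay_samples`, `quality` (peak normalized
#'   correlation) and `valid` (`FALSE` for flat windows).
#' @export
tap_delay <- function(ch1_window, ch2_window, fs,
                      max_lag = length(ch1_window) - 1L) {
  stopifnot(length(ch1_window) == length(ch2_window), fs > 0)
  if (sd(ch1_window) <= .Machine$double.eps ||
      sd(ch2_window) <= .Machine$double.eps) {
    return(list(delay_s = NA_real_, delay_samples = NA_real_,
                quality = NA_real_, valid = FALSE))
  }
  # windows are band-passed (zero-mean); skipping the mean subtraction keeps
  # the correlation of a pure shift exactly symmetric about its peak
  xc <- norm_xcorr(ch1_window, ch2_window, max_lag = max_lag, demean = FALSE)
  p <- which.max(xc$r)
  lag <- xc$lags[p]
  off <- if (p > 1L && p < length(xc$r)) {
    cosine_peak_offset(xc$r[p - 1L], xc$r[p], xc$r[p + 1L])
  } else 0
  d <- lag + off
  list(delay_s = d / fs, delay_samples = d, quality = xc$r[p], valid = TRUE)
}

#' Wave speed series from a tap recording
#'
#' Converts a (band-passed) two-channel recording into per-tap wave speeds:
#' for each detected tap, the travel time between channels is estimated over
#' the 4 ms window anchored at the tap time on channel 1, and speed =
#' `spacing / travel time`. Taps with non-positive delay, quality below
#' `quality_floor`, or speed outside `speed_bounds` are flagged invalid;
#' their speeds are linearly interpolated from valid neighbours for
#' downstream continuity, but the flag is retained.
#'
#' @param rec a band-passed [accel_recording()].
#' @param spacing axial accelerometer spacing in m.
#' @param quality_floor minimum peak correlation coefficient.
#' @param speed_bounds admissible speed range in m/s.
#' @param tap_times optional known tap times (s); detected when `NULL`.
#' @param window travel-time analysis window in s.
#' @param trial_id label used in error messages.
#' @param ... passed to [detect_taps()].
#' @return a `wave_speed_series` data.frame with columns `time_s`,
#'   `speed_mps`, `quality`, `valid`.
#' @export
wave_speed_series <- function(rec, spacing = 0.008, quality_floor = 0.5,
                              speed_bounds = c(2, 150), tap_times = NULL,
                              window = 0.004, trial_id = "trial", ...) {
  stopifnot(inherits(rec, "accel_recording"), spacing > 0)
  if (is.null(tap_times)) tap_times <- detect_taps(rec, ...)
  if (!length(tap_times)) {
    stop("no taps available in trial '", trial_id, "'")
  }
  L <- round(window * rec$fs)
  n <- length(rec$ch1)
  times <- speeds <- quality <- rep(NA_real_, length(tap_times))
  valid <- rep(FALSE, length(tap_times))
  for (k in seq_along(tap_times)) {
    i0 <- round((tap_times[k] - rec$start_time) * rec$fs) + 1L
    i1 <- i0 + L - 1L
    if (i0 < 1L || i1 > n) next
    est <- tap_delay(rec$ch1[i0:i1], rec$ch2[i0:i1], rec$fs,
                     max_lag = floor(L / 2))
    times[k] <- tap_times[k]
    quality[k] <- est$quality
    if (!est$valid || is.na(est$delay_s) || est$delay_s <= 0) next
    sp <- spacing / est$delay_s
    speeds[k] <- sp
    valid[k] <- est$quality >= quality_floor &&
      sp >= speed_bounds[1] && sp <= speed_bounds[2]
  }
  keep <- !is.na(times)
  times <- times[keep]; speeds <- speeds[keep]
  quality <- quality[keep]; valid <- valid[keep]
  if (!any(valid)) {
    stop("all taps invalid in trial '", trial_id,
         "'; check sensor contact / signal quality")
  }
  # interpolate invalid samples from valid neighbours, flags retained
  if (any(!valid)) {
    speeds[!valid] <- approx(times[valid], speeds[valid],
                             xout = times[!valid], rule = 2)$y
  }
  out <- data.frame(time_s = times, speed_mps = speeds,
                    quality = quality, valid = valid)
  class(out) <- c("wave_speed_series", "data.frame")
  out
}

#' Write / read a wave speed series as CSV
#'
#' @param ws a `wave_speed_series` data.frame.
#' @param path file path.
#' @return `read_wave_speed_csv` returns the `wave_speed_series`.
#' @export
write_wave_speed_csv <- function(ws, path) {
  write.csv(as.data.frame(ws), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wave_speed_csv
#' @export
read_wave_speed_csv <- function(path) {
  out <- read.csv(path)
  stopifnot(all(c("time_s", "speed_mps", "quality", "valid") %in% names(out)))
  class(out) <- c("wave_speed_series", "data.frame")
  out
}
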