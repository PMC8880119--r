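# Participant-specific calibration between squared Achilles wave speed and
# net ankle moment, fit from a balance-plate sway trial. A tensioned-beam
# model predicts tendon tension (hence ankle moment) proportional to squared
# shear wave speed, so the calibration is an ordinary least squares fit
# M = c1 * S^2 + c0.

#' Calibration model between squared wave speed and ankle moment
#'
#' @param c1 moment per unit squared wave speed, N m / (m/s)^2; must be > 0.
#' @param c0 intercept, N m.
#' @param r_squared coefficient of determination of the fit, in \[0, 1\].
#' @param n number of paired samples used.
#' @param participant participant label.
#' @return a `calibration_model` object.
#' @export
calibration_model <- function(c1, c0, r_squared = NA_real_, n = NA_integer_,
                              participant = NA_character_) {
  stopifnot(c1 > 0)
  if (!is.na(r_squared)) stopifnot(r_squared >= 0, r_squared <= 1)
  structure(list(c1 = c1, c0 = c0, r_squared = r_squared, n = n,
                 participant = participant),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration: M = %.4g * S^2 %+.4g N m, R^2 = %.3f (n = %s)>\n",
              x$c1, x$c0, x$r_squared, x$n))
  invisible(x)
}

#' Mean cohort calibration
#'
#' The cohort-mean wave-speed-to-moment map, `M = 0.05 S^2 - 17.0`
#' (N m from m/s), useful as a default when no participant-specific sway
#' fit is available.
#'
#' @return a [calibration_model()].
#' @export
mean_calibration <- function() calibration_model(c1 = 0.05, c0 = -17.0)

#' Align balance-plate and tensiometry clocks from a manual impact spike
#'
#' Both streams contain a sharp spike from a manual strike of the plate.
#' The spike is located in each stream (peak absolute deviation, required
#' to exceed `spike_mad` times the stream MAD), then the two spike regions
#' are cross-correlated for a subsample refinement. The returned offset is
#' the amount to add to the second stream's time axis so that the two
#' streams share the plate clock.
#'
#' @param plate_fz plate vertical-force samples (N).
#' @param other samples of the stream to align (wave speed or raw
#'   accelerometer magnitude) at the same rate.
#' @param fs common sample rate in Hz.
#' @param spike_mad spike detection threshold in multiples of the MAD.
#' @param window half-width of the correlation refinement window, s.
#' @return offset in seconds.
#' @export
align_plate_to_accel <- function(plate_fz, other, fs = 1000,
                                 spike_mad = 5, window = 0.1) {
  find_spike <- function(x, label) {
    # the strike is broadband and brief; slow sway is removed by a running
    # median so the spike stands out in the residual
    k <- min(2L * floor(0.025 * fs) + 1L, 2L * floor((length(x) - 1) / 2) + 1L)
    r <- x - runmed(x, k)
    # scale floor: the residual MAD of a smooth spike-free stream is ~0
    scale <- max(mad(r), 0.05 * sd(x), .Machine$double.eps)
    if (max(abs(r)) < spike_mad * scale) {
      stop("no impact spike found in ", label,
           " stream (need > ", spike_mad, "x MAD)")
    }
    which.max(abs(r))
  }
  ip <- find_spike(plate_fz, "plate")
  io <- find_spike(other, "accelerometer")
  coarse <- ip - io
  # refine: correlate detrended windows around each spike
  w <- round(window * fs)
  cut <- function(x, i) {
    i0 <- max(1L, i - w); i1 <- min(length(x), i + w)
    x[i0:i1]
  }
  a <- cut(plate_fz, ip); b <- cut(other, io)
  L <- min(length(a), length(b))
  xc <- norm_xcorr(scale(a[1:L])[, 1], scale(b[1:L])[, 1],
                   max_lag = min(w, L - 1L))
  p <- which.max(xc$r)
  off <- if (p > 1L && p < length(xc$r)) {
    cosine_peak_offset(xc$r[p - 1L], xc$r[p], xc$r[p + 1L])
  } else 0
  (coarse - (xc$lags[p] + off)) / fs
}

#' Net ankle moment from balance-plate streams
#'
#' `M(t) = Fz(t) * (COP_ap(t) - ankle_axis_ap)`: vertical force times the
#' anterior-posterior lever arm of the centre of pressure about the ankle
#' axis (the plate is positioned so the malleoli align with its mediolateral
#' axis).
#'
#' @param plate data.frame with columns `fz_n` and `cop_ap_m`.
#' @param ankle_axis_ap anterior-posterior ankle-axis position on the plate, m.
#' @return moment stream in N m.
#' @export
ankle_moment_from_plate <- function(plate, ankle_axis_ap = 0) {
  stopifnot(all(c("fz_n", "cop_ap_m") %in% names(plate)))
  plate$fz_n * (plate$cop_ap_m - ankle_axis_ap)
}

#' Fit the wave-speed-to-moment calibration
#'
#' Ordinary least squares of ankle moment on squared wave speed over
#' time-aligned, rate-matched paired samples.
#'
#' @param S wave speed samples, m/s.
#' @param M ankle moment samples, N m (same length as `S`).
#' @param min_samples minimum number of paired samples required.
#' @param participant participant label stored in the model.
#' @return a [calibration_model()].
#' @export
fit_calibration <- function(S, M, min_samples = 100,
                            participant = NA_character_) {
  stopifnot(length(S) == length(M))
  keep <- is.finite(S) & is.finite(M)
  S <- S[keep]; M <- M[keep]
  if (length(S) < min_samples) {
    stop("need at least ", min_samples, " paired samples, got ", length(S))
  }
  s2 <- S^2
  if (var(s2) < 1e-12 * max(1, mean(s2)^2)) {
    stop("degenerate design: squared wave speed is (near-)constant")
  }
  fit <- lm(M ~ s2)
  ss_tot <- sum((M - mean(M))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  calibration_model(c1 = unname(coef(fit)[2]), c0 = unname(coef(fit)[1]),
                    r_squared = min(1, max(0, r2)), n = length(S),
                    participant = participant)
}

#' Convert wave speed to ankle moment
#'
#' @param S wave speed, m/s (>= 0).
#' @param model a [calibration_model()].
#' @return moment in N m: `c1 * S^2 + c0`.
#' @export
moment_from_wave_speed <- function(S, model = mean_calibration()) {
  if (any(S < 0, na.rm = TRUE)) stop("wave speed must be non-negative")
  model$c1 * S^2 + model$c0
}

#' Convert ankle moment to wave speed (calibration inverse)
#'
#' @param M moment in N m; must satisfy `M >= c0`.
#' @param model a [calibration_model()].
#' @return wave speed in m/s: `sqrt((M - c0) / c1)`.
#' @export
wave_speed_from_moment <- function(M, model = mean_calibration()) {
  if (any(M < model$c0, na.rm = TRUE)) {
    stop("moment below the calibration intercept floor (", model$c0,
         " N m); squared wave speed would be negative")
  }
  sqrt((M - model$c0) / model$c1)
}

#' Compare pre- and post-session calibrations
#'
#' Reports relative coefficient changes between two sway-trial fits and
#' flags drift when either exceeds the threshold, supporting the protocol
#' of repeating the sway trial at the end of a session to verify that the
#' calibration held.
#'
#' @param pre,post [calibration_model()]s.
#' @param threshold relative drift threshold (default 0.15 = 15%).
#' @return list with `delta_c1_rel`, `delta_c0_rel` and logical `drift`.
#' @export
compare_calibrations <- function(pre, post, threshold = 0.15) {
  d1 <- (post$c1 - pre$c1) / pre$c1
  d0 <- (post$c0 - pre$c0) / max(abs(pre$c0), .Machine$double.eps)
  list(delta_c1_rel = d1, delta_c0_rel = d0,
       drift = abs(d1) > threshold || abs(d0) > threshold)
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model a [calibration_model()].
#' @param path file path.
#' @return `read_calibration_json` returns the [calibration_model()].
#' @export
write_calibration_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(x$c1, x$c0,
                    r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared,
                    n = if (is.null(x$n)) NA_integer_ else x$n,
                    participant = if (is.null(x$participant)) NA_character_ else x$participant)
}
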