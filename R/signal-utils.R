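# Shared low-level signal helpers: normalized cross-correlation, subsample
# peak interpolation, band-limited fractional shifting, smooth template
# interpolation. These are the numerical primitives the wave-speed and
# alignment estimators are built on.

#' Normalized cross-correlation over a lag range
#'
#' Computes the normalized cross-correlation \eqn{r(\lambda) = \sum_i a_i
#' b_{i+\lambda} / \sqrt{\sum a_i^2 \sum b_i^2}} between two equal-length,
#' mean-removed windows for integer lags in `-max_lag:max_lag`. Positive lags
#' mean `b` is delayed relative to `a`.
#'
#' @param a,b numeric vectors of equal length.
#' @param max_lag maximum absolute integer lag to evaluate.
#' @param demean subtract each window's mean first (default `TRUE`).
#' @return list with `lags` (integer vector) and `r` (correlation values);
#'   windows with zero variance yield `NA` correlations.
#' @export
norm_xcorr <- function(a, b, max_lag = length(a) - 1L, demean = TRUE) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  max_lag <- min(as.integer(max_lag), length(a) - 1L)
  if (demean) {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  denom <- sqrt(sum(a^2) * sum(b^2))
  lags <- seq.int(-max_lag, max_lag)
  if (denom <= .Machine$double.eps) {
    return(list(lags = lags, r = rep(NA_real_, length(lags))))
  }
  n <- length(a)
  # FFT-based full cross-correlation, then crop to the requested lag range
  nfft <- stats::nextn(2L * n, 2L)
  fa <- fft(c(a, rep(0, nfft - n)))
  fb <- fft(c(b, rep(0, nfft - n)))
  cc <- Re(fft(Conj(fa) * fb, inverse = TRUE)) / nfft
  # lag k (b delayed by k) lives at index k+1 (mod nfft)
  r <- cc[((lags %% nfft)) + 1L] / denom
  list(lags = lags, r = r)
}

#' Cosine interpolation of a correlation peak
#'
#' Fits \eqn{r(\delta) = A\cos(\omega\delta + \theta)} through a correlation
#' peak sample and its two neighbours and returns the subsample offset of the
#' true maximum, in samples, relative to the centre point. This cosine fit
#' gives the delay estimator its subsample resolution; a parabolic fit is
#' used as fallback when the cosine model is degenerate (e.g. the three
#' points do not bracket a strict maximum of a cosine).
#'
#' @param r1,r2,r3 correlation at the sample before, at, and after the peak.
#' @return subsample offset in (-1, 1); 0 when the fit is degenerate.
#' @export
cosine_peak_offset <- function(r1, r2, r3) {
  if (!all(is.finite(c(r1, r2, r3))) || r2 == 0) return(0)
  arg <- (r1 + r3) / (2 * r2)
  if (abs(arg) < 1) {
    omega <- acos(arg)
    if (omega > .Machine$double.eps) {
      theta <- atan2((r1 - r3) / (2 * sin(omega)), r2)
      off <- -theta / omega
      if (is.finite(off) && abs(off) < 1) return(off)
    }
  }
  # parabolic fallback
  den <- r1 - 2 * r2 + r3
  if (abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (r1 - r3) / den
  max(-1, min(1, off))
}

#' Band-limited fractional-sample shift
#'
#' Delays a uniformly sampled signal by an arbitrary (fractional) number of
#' samples using a frequency-domain phase ramp. The shift is exact for
#' band-limited content; wrap-around is circular, so callers should pad
#' signals whose support approaches the ends.
#'
#' @param x numeric vector.
#' @param shift delay in samples (positive = later in time); may be fractional.
#' @return shifted numeric vector of the same length.
#' @export
fractional_shift <- function(x, shift) {
  n <- length(x)
  if (shift == 0 || n < 2) return(x)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  ph <- exp(-2i * pi * k * shift / n)
  if (n %% 2 == 0) ph[n / 2 + 1] <- Re(ph[n / 2 + 1]) # keep Nyquist bin real
  Re(fft(fft(x) * ph, inverse = TRUE)) / n
}

# Smooth piecewise-cosine interpolation through knots (C1 except flat
# derivative at knots); used for periodic gait templates.
cosine_segments <- function(knot_x, knot_y, x) {
  stopifnot(length(knot_x) == length(knot_y), !is.unsorted(knot_x))
  idx <- findInterval(x, knot_x, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx >= length(knot_x)] <- length(knot_x) - 1L
  x0 <- knot_x[idx]; x1 <- knot_x[idx + 1L]
  y0 <- knot_y[idx]; y1 <- knot_y[idx + 1L]
  u <- (x - x0) / (x1 - x0)
  y0 + (y1 - y0) * (1 - cos(pi * u)) / 2
}

# Greedy peak picking: local maxima above `height`, enforcing a minimum
# separation by keeping the stronger of any conflicting pair.
pick_peaks <- function(x, height, min_sep) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= height]
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  ord <- order(x[cand], decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) >= min_sep)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  sort(cand[keep])
}

# Linear resample of (t, y) onto a new time grid, constant-extrapolated.
resample_linear <- function(t, y, t_out) {
  approx(t, y, xout = t_out, rule = 2)$y
}
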