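# Inter-system clock alignment. The kinematic (IMU) and tensiometry
# recordings start a non-deterministic 10-100 ms apart (wireless trigger
# jitter). Over level strides, the ankle-angle and wave-speed streams rise
# together through early stance, so cross-correlating the two over the
# first 10% of each gait cycle recovers the start delay; the mean across
# level strides is applied to put both streams on one clock.

#' Estimate the inter-system start offset from level strides
#'
#' For each level stride (|slope| below `level_tol`), the wave-speed curve
#' over the first `window_fraction` of the gait cycle is cross-correlated
#' against the ankle-flexion angle, with both z-scored, over lags within
#' `max_lag`; the per-stride lag is the (cosine-refined) correlation argmax.
#' The mean lag across level strides is the estimated delay of the
#' tensiometry stream relative to the kinematics: adding it to the
#' tensiometry time axis (see [apply_offset()]) puts both streams on the
#' kinematics clock.
#'
#' @param kin data.frame with `time_s` and `ankle_deg` (kinematics clock).
#' @param ws data.frame with `time_s` and `speed_mps` (tensiometry clock).
#' @param heel_strikes stride-splitting heel-strike times on the
#'   tensiometry clock.
#' @param slopes per-stride terrain slope in degrees
#'   (`length(heel_strikes) - 1`).
#' @param window_fraction fraction of the gait cycle used (default 0.10).
#' @param level_only use only level strides (default `TRUE`; `FALSE` uses
#'   all strides).
#' @param level_tol level-stride threshold in degrees.
#' @param max_lag lag search bound in s.
#' @param min_strides minimum number of usable strides.
#' @return a `sync_estimate` list: `per_stride_lags` (s), `mean_offset` (s),
#'   `n_strides_used`.
#' @export
estimate_sync_offset <- function(kin, ws, heel_strikes, slopes,
                                 window_fraction = 0.10, level_only = TRUE,
                                 level_tol = 1, max_lag = 0.15,
                                 min_strides = 5) {
  stopifnot(all(c("time_s", "ankle_deg") %in% names(kin)),
            all(c("time_s", "speed_mps") %in% names(ws)),
            length(slopes) == length(heel_strikes) - 1L)
  use <- if (level_only) abs(slopes) < level_tol else rep(TRUE, length(slopes))
  # strides must leave room for the lag search inside both streams
  use <- use & head(heel_strikes, -1) - max_lag >= min(kin$time_s) &
    tail(heel_strikes, -1) <= max(ws$time_s)
  idx <- which(use)
  if (length(idx) < min_strides) {
    stop("need at least ", min_strides, " level strides for sync ",
         "estimation, found ", length(idx),
         "; collect more level walking or lower level_tol")
  }
  dt <- median(diff(kin$time_s))
  K <- ceiling(max_lag / dt)
  lags_s <- numeric(length(idx))
  zs <- function(x) {
    s <- sd(x)
    if (s <= .Machine$double.eps) rep(0, length(x)) else (x - mean(x)) / s
  }
  for (j in seq_along(idx)) {
    i <- idx[j]
    t0 <- heel_strikes[i]
    Tt <- heel_strikes[i + 1L] - t0
    u <- seq(0, window_fraction * Tt, by = dt)
    w <- zs(resample_linear(ws$time_s, ws$speed_mps, t0 + u))
    r <- vapply(-K:K, function(k) {
      a <- zs(resample_linear(kin$time_s, kin$ankle_deg, t0 + u + k * dt))
      mean(w * a)
    }, numeric(1))
    p <- which.max(r)
    off <- if (p > 1L && p < length(r)) {
      cosine_peak_offset(r[p - 1L], r[p], r[p + 1L])
    } else 0
    lags_s[j] <- ((-K:K)[p] + off) * dt
  }
  structure(list(per_stride_lags = lags_s, mean_offset = mean(lags_s),
                 n_strides_used = length(idx)),
            class = "sync_estimate")
}

#' @export
print.sync_estimate <- function(x, ...) {
  cat(sprintf("<sync: mean offset %+.1f ms over %d level strides (sd %.1f ms)>\n",
              1000 * x$mean_offset, x$n_strides_used,
              1000 * sd(x$per_stride_lags)))
  invisible(x)
}

#' Shift a time series by a clock offset
#'
#' Adds `offset` to the series' time axis and drops samples that leave the
#' original time span, so repeated application with `+d` then `-d` restores
#' the series on the overlap.
#'
#' @param series data.frame with a `time_s` column, or a numeric time vector.
#' @param offset offset in s.
#' @return the shifted series (same type as input).
#' @export
apply_offset <- function(series, offset) {
  if (is.numeric(series)) return(series + offset)
  stopifnot("time_s" %in% names(series))
  lo <- min(series$time_s); hi <- max(series$time_s)
  t_new <- series$time_s + offset
  keep <- t_new >= lo - 1e-12 & t_new <= hi + 1e-12
  out <- series[keep, , drop = FALSE]
  out$time_s <- t_new[keep]
  rownames(out) <- NULL
  out
}
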