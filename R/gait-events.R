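# Stride segmentation and terrain-slope assignment: heel-strike detection
# from band-passed accelerometry, spatiotemporal stride metrics with
# exclusion rules, course-map construction from two mapping passes, and
# per-stride slope lookup with 2-degree binning.

#' Detect heel strikes from accelerometry
#'
#' Band-passes the accelerometer trace to the impact band (10-50 Hz) with a
#' zero-phase Butterworth filter and takes prominent peaks separated by at
#' least a minimum stride time as approximate heel-strike events. The peak
#' height threshold adapts to the stream (multiples of its MAD).
#'
#' @param accel numeric acceleration samples (typically the tensiometer's
#'   distal accelerometer, decimated) or an [accel_recording()] (channel 2
#'   used).
#' @param fs sample rate in Hz (ignored when `accel` is a recording).
#' @param band impact band in Hz; the upper edge is clamped below Nyquist.
#' @param min_stride minimum stride time in s; of two closer peaks the
#'   higher one is kept.
#' @param prominence_mad peak height threshold in multiples of the filtered
#'   stream's MAD.
#' @param rel_floor additional height floor as a fraction of the largest
#'   absolute filtered sample (impact bursts are sparse, so the MAD alone
#'   under-estimates the noise floor between strides).
#' @param order overall Butterworth order.
#' @return heel-strike times in s; empty (with a warning) when none found.
#' @export
detect_heel_strikes <- function(accel, fs, band = c(10, 50), min_stride = 0.4,
                                prominence_mad = 2, rel_floor = 0.3,
                                order = 4) {
  start_time <- 0
  if (inherits(accel, "accel_recording")) {
    fs <- accel$fs
    start_time <- accel$start_time
    accel <- accel$ch2
  }
  stopifnot(fs > 0, length(band) == 2, band[1] > 0)
  hi <- min(band[2], 0.45 * fs)
  if (hi <= band[1]) stop("impact band does not fit below Nyquist")
  bf <- signal::butter(order / 2, c(band[1], hi) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bf, accel))
  thr <- max(prominence_mad * mad(xf), rel_floor * max(abs(xf)), 1e-12)
  peaks <- pick_peaks(xf, height = thr, min_sep = round(min_stride * fs))
  if (!length(peaks)) {
    warning("no heel strikes detected")
    return(numeric(0))
  }
  start_time + (peaks - 1L) / fs
}

#' Spatiotemporal stride metrics
#'
#' Splits a trial into strides at heel strikes and computes stride time,
#' stride length (total horizontal pelvis displacement between heel
#' strikes) and walking speed (their quotient). Strides longer than
#' `max_length` are marked excluded with reason `"stride_length_gt_3m"`
#' (IMU reconstruction errors inflate displacement).
#'
#' @param kin data.frame with columns `time_s` and `pelvis_x_m`.
#' @param heel_strikes strictly increasing heel-strike times, length >= 2.
#' @param max_length stride-length exclusion threshold in m.
#' @return a `stride_table` data.frame: `stride_id`, `start_s`, `end_s`,
#'   `stride_time_s`, `stride_length_m`, `speed_mps`, `midpoint_x_m`,
#'   `slope_deg`, `slope_bin`, `included`, `exclusion_reason`.
#' @export
stride_metrics <- function(kin, heel_strikes, max_length = 3.0) {
  stopifnot(all(c("time_s", "pelvis_x_m") %in% names(kin)))
  if (length(heel_strikes) < 2) stop("need at least two heel strikes")
  if (is.unsorted(heel_strikes, strictly = TRUE)) {
    stop("heel-strike times must be strictly increasing")
  }
  x_at <- function(t) resample_linear(kin$time_s, kin$pelvis_x_m, t)
  start <- head(heel_strikes, -1)
  end <- tail(heel_strikes, -1)
  len <- x_at(end) - x_at(start)
  st <- end - start
  excl <- ifelse(len > max_length, "stride_length_gt_3m", NA_character_)
  out <- data.frame(stride_id = seq_along(start), start_s = start,
                    end_s = end, stride_time_s = st, stride_length_m = len,
                    speed_mps = len / st,
                    midpoint_x_m = x_at((start + end) / 2),
                    slope_deg = NA_real_, slope_bin = NA_real_,
                    included = is.na(excl), exclusion_reason = excl)
  class(out) <- c("stride_table", "data.frame")
  out
}

#' Build a course incline map from out-and-back mapping passes
#'
#' Rescales each pass's displacement axis to the known one-way course
#' length, mirrors the return pass onto outward coordinates with its incline
#' sign flipped, averages the two incline measurements at each grid
#' position, and applies a moving 2-m median filter.
#'
#' @param pass_out,pass_back data.frames with columns `displacement_m`
#'   (cumulative, from each pass's own start) and `incline_deg`.
#' @param known_length known one-way course length in m.
#' @param median_window moving-median window in m.
#' @param grid_step output grid spacing in m.
#' @return a one-way `course_map` data.frame (`position_m`, `incline_deg`);
#'   attribute `one_way` is `TRUE`, so slope lookups fold out-and-back
#'   displacements onto it.
#' @export
build_course_map <- function(pass_out, pass_back, known_length,
                             median_window = 2.0, grid_step = 0.5) {
  stopifnot(known_length > 0)
  cov_out <- max(pass_out$displacement_m)
  cov_back <- max(pass_back$displacement_m)
  if (abs(cov_out - cov_back) / cov_out > 0.10) {
    stop("mapping passes cover grossly unequal lengths (",
         signif(cov_out, 4), " vs ", signif(cov_back, 4), " m)")
  }
  pos <- seq(0, known_length, by = grid_step)
  out_i <- resample_linear(pass_out$displacement_m * known_length / cov_out,
                           pass_out$incline_deg, pos)
  # return pass: position folds back, incline sign flips
  back_i <- resample_linear(pass_back$displacement_m * known_length / cov_back,
                            pass_back$incline_deg, known_length - pos)
  incline <- (out_i - back_i) / 2
  k <- 2L * floor(median_window / grid_step / 2) + 1L
  if (k >= 3 && length(incline) > k) incline <- runmed(incline, k)
  map <- data.frame(position_m = pos, incline_deg = as.numeric(incline))
  class(map) <- c("course_map", "data.frame")
  attr(map, "one_way") <- TRUE
  map
}

#' Nearest-even-degree slope bin
#'
#' Bins slopes to even-degree centres (-10, -8, ..., +10) by nearest centre
#' with ties resolved toward zero, and clamps to the bin range.
#'
#' @param slope_deg slopes in degrees.
#' @param bin_width bin width in degrees.
#' @param max_bin extreme bin centre magnitude.
#' @return bin centres in degrees.
#' @export
slope_bin <- function(slope_deg, bin_width = 2, max_bin = 10) {
  b <- sign(slope_deg) * bin_width *
    ceiling(abs(slope_deg) / bin_width - 0.5)
  pmin(max_bin, pmax(-max_bin, b)) + 0 # drop -0
}

#' Assign terrain slope and slope bin to strides
#'
#' Looks up the course incline at each stride's midpoint cumulative pelvis
#' displacement and bins it to even-degree centres. For one-way maps (from
#' [build_course_map()]) displacements beyond the one-way length are folded
#' back onto the map with the incline sign flipped (the return pass walks
#' the hill in the opposite direction). Strides whose midpoint falls outside
#' the mapped course are excluded with reason `"off_course"`.
#'
#' @param strides a `stride_table` from [stride_metrics()].
#' @param map a `course_map` (from [make_course()] or [build_course_map()]).
#' @param displacement_m optional explicit midpoint displacements; default
#'   is the table's `midpoint_x_m`.
#' @param bin_width bin width in degrees.
#' @return the stride table with `slope_deg`, `slope_bin`, `included` and
#'   `exclusion_reason` updated.
#' @export
assign_and_bin_slope <- function(strides, map, displacement_m = NULL,
                                 bin_width = 2) {
  if (inherits(map, "course")) map <- map$map
  if (is.null(displacement_m)) displacement_m <- strides$midpoint_x_m
  stopifnot(length(displacement_m) == nrow(strides))
  one_way <- isTRUE(attr(map, "one_way"))
  pmax_map <- max(map$position_m)
  span <- if (one_way) 2 * pmax_map else pmax_map
  p <- displacement_m
  off <- p < min(map$position_m) - 1e-9 | p > span + 1e-9
  sl <- rep(NA_real_, length(p))
  if (one_way) {
    folded <- ifelse(p > pmax_map, 2 * pmax_map - p, p)
    sgn <- ifelse(p > pmax_map, -1, 1)
    sl[!off] <- sgn[!off] *
      resample_linear(map$position_m, map$incline_deg, folded[!off])
  } else {
    sl[!off] <- resample_linear(map$position_m, map$incline_deg, p[!off])
  }
  strides$slope_deg <- sl
  strides$slope_bin <- slope_bin(sl, bin_width)
  newly_off <- off & is.na(strides$exclusion_reason)
  strides$exclusion_reason[newly_off] <- "off_course"
  strides$included <- is.na(strides$exclusion_reason)
  strides
}
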