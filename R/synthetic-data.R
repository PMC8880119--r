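# Synthetic gait-and-sensor generator. Emulates the wearable study setup:
# an out-and-back sloped course, slope-modulated joint kinematics and ankle
# moment over the gait cycle, tendon-tap accelerometer recordings at the
# tensiometer rate, balance-plate sway trials for calibration, and a cohort
# work set with a configurable piecewise-linear slope-to-work law. Ground
# truth is retained alongside every output.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Participant profile
#'
#' Bundles the per-participant constants the generator and pipeline need:
#' body mass, the participant's true wave-speed-to-moment calibration
#' (moment `= calib_slope * S^2 + calib_intercept`), and level-ground gait
#' scale. Defaults are the cohort means of the study population this
#' generator emulates (76.5 kg, calibration 0.05/-17.0, level stride length
#' 1.60 m at 1.31 m/s).
#'
#' @param id participant label.
#' @param mass body mass in kg (> 0).
#' @param calib_slope moment per unit squared wave speed, N m / (m/s)^2 (> 0).
#' @param calib_intercept calibration intercept, N m.
#' @param level_stride_length level-ground stride length in m, in (0, 3].
#' @param level_speed level-ground walking speed in m/s (> 0).
#' @return a `participant_profile` list.
#' @export
participant_profile <- function(id = "P01", mass = 76.5,
                                calib_slope = 0.05, calib_intercept = -17.0,
                                level_stride_length = 1.60, level_speed = 1.31) {
  stopifnot(mass > 0, calib_slope > 0,
            level_stride_length > 0, level_stride_length <= 3,
            level_speed > 0)
  structure(list(id = id, mass = mass, calib_slope = calib_slope,
                 calib_intercept = calib_intercept,
                 level_stride_length = level_stride_length,
                 level_speed = level_speed),
            class = "participant_profile")
}

#' Default gait pattern templates
#'
#' Phenomenological periodic templates of ankle dorsiflexion, knee flexion
#' (degrees) and net ankle plantarflexion moment (N m) versus gait-cycle
#' fraction, with slope modulators. Shapes follow the canonical walking
#' pattern: dorsiflexion rising through stance then rapid plantarflexion at
#' push-off; a double-humped knee flexion curve; a single-peaked stance
#' moment. Both the moment and ankle-angle templates carry a shared
#' loading-response bump, symmetric about 5% of the cycle, over the first
#' 10% (impact loading co-occurs with the heel rocker): any monotone
#' transform of a symmetric feature stays symmetric about the same point,
#' so cross-correlating wave speed with ankle angle over that window has
#' its optimum exactly at zero lag, which is what makes the level-stride
#' clock aligner unbiased. Slope modulators scale the moment peak, shift the ankle curve,
#' and lengthen strides with incline while walking speed stays constant.
#'
#' @param moment_template optional replacement moment knot values (N m) on
#'   the same phase knots as the default; a single number gives a constant
#'   moment template (useful for analytic checks).
#' @return a `gait_pattern` list of knot vectors and modulator coefficients.
#' @export
gait_pattern_default <- function(moment_template = NULL) {
  pat <- list(
    ankle_x = c(0, 0.05, 0.10, 0.45, 0.65, 0.85, 1),
    ankle_y = c(0, 5, 0, 10, -15, 0, 0),
    knee_x = c(0, 0.15, 0.4, 0.75, 0.9, 1),
    knee_y = c(5, 20, 8, 65, 8, 5),
    # moment peaks just after the ankle-angle peak (push-off begins while
    # force is still high), giving the force-excursion loop positive area
    moment_x = c(0, 0.05, 0.10, 0.50, 0.62, 0.8, 1),
    moment_y = c(5, 35, 5, 90, 2, 2, 5),
    modulators = list(
      moment_scale_per_deg = 0.03,   # fractional moment-peak gain per degree
      ankle_shift_per_deg = 0.25,    # degrees of stance ankle shift per degree
      knee_shift_per_absdeg = 0.5,   # degrees of knee flexion per |degree|
      stride_length_per_deg = 0.0075 # fractional stride-length gain per degree
    )
  )
  if (!is.null(moment_template)) {
    if (length(moment_template) == 1) {
      pat$moment_y <- rep(moment_template, length(pat$moment_x))
    } else {
      stopifnot(length(moment_template) == length(pat$moment_x))
      pat$moment_y <- moment_template
    }
  }
  stopifnot(abs(pat$ankle_y[1] - pat$ankle_y[length(pat$ankle_y)]) < 1e-9,
            all(pat$moment_y >= 0))
  structure(pat, class = "gait_pattern")
}

#' Trial specification
#'
#' @param n_strides number of strides to generate.
#' @param slope_sequence terrain slope per stride in degrees, within
#'   \[-10, 10\]; recycled if scalar.
#' @param sync_delay inter-system start delay in seconds, within \[0, 0.1\]:
#'   the tensiometry stream starts this much later than the kinematics.
#' @param noise_scale measurement-noise amplitude as a fraction of signal
#'   amplitude (0 disables noise).
#' @param seed integer RNG seed; fixed seed gives bit-reproducible trials.
#' @return a `trial_spec` list.
#' @export
trial_spec <- function(n_strides, slope_sequence = 0, sync_delay = 0,
                       noise_scale = 0, seed = 1L) {
  stopifnot(n_strides >= 1, all(abs(slope_sequence) <= 10),
            sync_delay >= 0, sync_delay <= 0.1, noise_scale >= 0)
  structure(list(n_strides = as.integer(n_strides),
                 slope_sequence = rep_len(as.numeric(slope_sequence), n_strides),
                 sync_delay = sync_delay, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "trial_spec")
}

#' Generate a synthetic out-and-back sloped course
#'
#' Builds a piecewise-smooth incline profile for an out-and-back course:
#' the outward half is divided into sections whose inclines are drawn to
#' cover every 2-degree slope bin up to `max_slope` (section targets cycle
#' through the bin centres with sub-bin jitter), and the return half mirrors
#' the outward half with the sign flipped, so that incline at position `p`
#' equals minus the incline at `total_length - p`.
#'
#' @param total_length full out-and-back length in m (> 0).
#' @param max_slope maximum absolute incline in degrees (<= 10).
#' @param section_length length of each constant-incline section in m.
#' @param seed integer seed controlling section order, signs and jitter.
#' @param grid_step map grid spacing in m.
#' @return a `course` list: `map` (data.frame `position_m`, `incline_deg`,
#'   class `course_map`), `sections` (section table for both passes; the
#'   return pass mirrors the outward pass with inclines sign-flipped), and
#'   the generating parameters.
#' @export
make_course <- function(total_length = 800, max_slope = 10,
                        section_length = 50, seed = 1L, grid_step = 0.5) {
  if (total_length <= 0) stop("total_length must be positive")
  if (section_length <= 0) stop("section_length must be positive")
  stopifnot(abs(max_slope) <= 10)
  half <- total_length / 2
  n_sec <- max(1L, ceiling(half / section_length))
  mags <- seq(0, max_slope, by = 2)
  if (max_slope == 0) mags <- 0
  with_seed(seed, {
    pool <- rep_len(mags, n_sec)
    pool <- sample(pool)
    jit_amp <- min(0.8, 0.08 * max_slope)
    jitter <- runif(n_sec, -jit_amp, jit_amp)
    signs <- sample(c(-1, 1), n_sec, replace = TRUE)
    inc <- signs * pmin(max_slope, pmax(0, pool + jitter))
  })
  bounds <- seq(0, half, length.out = n_sec + 1)
  sections <- data.frame(
    start_m = c(bounds[-length(bounds)], total_length - rev(bounds[-1])),
    end_m = c(bounds[-1], total_length - rev(bounds[-length(bounds)])),
    incline_deg = c(inc, -rev(inc)),
    pass = rep(c("out", "back"), each = n_sec))
  # smooth transitions between sections over +/- ramp metres
  ramp <- min(5, section_length / 4)
  kx <- 0; ky <- inc[1]
  if (n_sec > 1) {
    b <- bounds[2:n_sec]
    kx <- c(0, as.vector(rbind(b - ramp, b + ramp)), half)
    ky <- c(inc[1], as.vector(rbind(inc[-n_sec], inc[-1])), inc[n_sec])
  } else {
    kx <- c(0, half); ky <- c(inc, inc)
  }
  pos <- seq(0, total_length, by = grid_step)
  out_mask <- pos <= half
  incline <- numeric(length(pos))
  incline[out_mask] <- cosine_segments(kx, ky, pos[out_mask])
  incline[!out_mask] <- -cosine_segments(kx, ky, total_length - pos[!out_mask])
  map <- data.frame(position_m = pos, incline_deg = incline)
  class(map) <- c("course_map", "data.frame")
  structure(list(map = map, sections = sections,
                 total_length = total_length, max_slope = max_slope,
                 section_length = section_length, seed = seed),
            class = "course")
}

#' Query course incline at positions
#'
#' @param course a `course` from [make_course()] or a `course_map`
#'   data.frame.
#' @param position_m positions along the course in m.
#' @return incline in degrees, linearly interpolated from the map grid.
#' @export
course_incline <- function(course, position_m) {
  map <- if (inherits(course, "course")) course$map else course
  resample_linear(map$position_m, map$incline_deg, position_m)
}

# Evaluate slope-modulated gait templates at arbitrary times.
# hs: heel-strike times (n_strides + 1); slopes: per-stride slope (deg).
eval_gait <- function(t, pattern, hs, slopes) {
  n_str <- length(hs) - 1L
  idx <- findInterval(t, hs, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > n_str] <- n_str
  phase <- (t - hs[idx]) / (hs[idx + 1L] - hs[idx])
  phase <- pmin(1, pmax(0, phase))
  s <- slopes[idx]
  mod <- pattern$modulators
  stance_w <- cosine_segments(c(0, 0.15, 0.45, 0.65, 1), c(0.6, 1, 1, 0, 0), phase)
  ankle <- cosine_segments(pattern$ankle_x, pattern$ankle_y, phase) +
    mod$ankle_shift_per_deg * s * stance_w
  knee <- cosine_segments(pattern$knee_x, pattern$knee_y, phase) +
    mod$knee_shift_per_absdeg * abs(s) * stance_w
  moment <- cosine_segments(pattern$moment_x, pattern$moment_y, phase) *
    (1 + mod$moment_scale_per_deg * s)
  moment <- pmax(moment, 0)
  list(ankle_deg = ankle, knee_deg = knee, moment_nm = moment, phase = phase,
       stride = idx)
}

#' Generate a synthetic walking trial
#'
#' Produces slope-modulated joint-kinematics streams at the IMU rate, the
#' matching true ankle-moment stream, the true Achilles wave-speed stream
#' obtained by inverting the participant's calibration
#' (`S = sqrt((M - c0) / c1)`), and true heel-strike times. The wave-speed
#' stream is emitted on its own clock, which starts `spec$sync_delay`
#' seconds later than the kinematics clock (its sample at time `t` reflects
#' kinematic time `t + sync_delay`), emulating the non-deterministic
#' wireless trigger delay between the two recording systems.
#'
#' @param profile a [participant_profile()].
#' @param pattern a [gait_pattern_default()] pattern.
#' @param spec a [trial_spec()].
#' @param fs_imu kinematics/wave-speed sample rate in Hz.
#' @return a `gait_trial` list: `kinematics` (data.frame `time_s`,
#'   `ankle_deg`, `knee_deg`, `pelvis_x_m`), `wave_speed` (data.frame
#'   `time_s`, `speed_mps` on the delayed tensiometry clock) and `truth`
#'   (heel strikes, per-stride slopes/lengths/times, noise-free moment and
#'   wave-speed streams on the kinematics clock, injected `sync_delay`).
#' @export
make_trial <- function(profile, pattern = gait_pattern_default(), spec,
                       fs_imu = 100) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(spec, "trial_spec"))
  s <- spec$slope_sequence
  mod <- pattern$modulators
  stride_len <- profile$level_stride_length * (1 + mod$stride_length_per_deg * s)
  stride_time <- stride_len / profile$level_speed
  hs <- cumsum(c(0, stride_time))
  total <- hs[length(hs)]
  t_kin <- seq(0, total, by = 1 / fs_imu)
  g <- eval_gait(t_kin, pattern, hs, s)
  # moment -> true wave speed via inverted calibration
  m_shift <- g$moment_nm - profile$calib_intercept
  if (any(m_shift <= 0)) {
    stop("moment template falls below the calibration intercept floor; ",
         "squared wave speed would be non-positive (min shifted moment ",
         signif(min(m_shift), 3), " N m)")
  }
  speed_true <- sqrt(m_shift / profile$calib_slope)
  # pelvis advances linearly within each stride
  pelvis <- cumsum(c(0, stride_len))[g$stride] + g$phase * stride_len[g$stride]
  # tensiometry clock starts sync_delay later
  t_ws <- seq(0, total - spec$sync_delay, by = 1 / fs_imu)
  g_ws <- eval_gait(t_ws + spec$sync_delay, pattern, hs, s)
  speed_ws <- sqrt((g_ws$moment_nm - profile$calib_intercept) /
                     profile$calib_slope)
  ankle <- g$ankle_deg; knee <- g$knee_deg
  if (spec$noise_scale > 0) {
    with_seed(spec$seed, {
      ang_sd <- min(0.25, spec$noise_scale * diff(range(ankle)))
      ankle <- ankle + rnorm(length(ankle), 0, ang_sd)
      knee <- knee + rnorm(length(knee), 0, ang_sd)
      speed_ws <- speed_ws +
        rnorm(length(speed_ws), 0, spec$noise_scale * max(speed_true))
    })
  }
  structure(list(
    kinematics = data.frame(time_s = t_kin, ankle_deg = ankle,
                            knee_deg = knee, pelvis_x_m = pelvis),
    wave_speed = data.frame(time_s = t_ws, speed_mps = speed_ws),
    truth = list(heel_strikes = hs, stride_slopes = s,
                 stride_lengths = stride_len, stride_times = stride_time,
                 moment = data.frame(time_s = t_kin, moment_nm = g$moment_nm),
                 wave_speed = data.frame(time_s = t_kin,
                                         speed_mps = speed_true),
                 sync_delay = spec$sync_delay),
    profile = profile, fs_imu = fs_imu), class = "gait_trial")
}

# Raised-cosine windowed tone burst: the tap wavelet. Amplitude ~1,
# duration `dur` s, centre frequency inside the 150-1500 Hz analysis band.
tap_wavelet_fun <- function(t, dur = 0.002, freq = 800) {
  ifelse(t >= 0 & t <= dur,
         sin(2 * pi * freq * t) * 0.5 * (1 - cos(2 * pi * t / dur)),
         0)
}

#' Render a two-channel tendon-tap accelerometer recording
#'
#' Synthesizes the tensiometer's raw signal: channel 1 carries a 2 ms
#' raised-cosine tone burst at each tap time; channel 2 carries the same
#' burst attenuated and delayed by `spacing / S(t)` where `S` is the true
#' wave speed at the tap time. Delays are realized by evaluating the
#' continuous wavelet at shifted sample times, so subsample delays are
#' exact. Additive white noise is scaled as a fraction of the wavelet
#' amplitude, with channel 2 noisier (attenuation lowers its SNR).
#'
#' @param wave_speed data.frame (`time_s`, `speed_mps`): true wave speed.
#' @param fs accelerometer sample rate in Hz.
#' @param spacing axial accelerometer spacing in m.
#' @param tap_interval time between taps in s.
#' @param noise_scale noise standard deviation as a fraction of the channel-1
#'   wavelet amplitude (e.g. `3.2e-5` for 0.0032%); must be >= 0.
#' @param seed integer RNG seed for the noise.
#' @param attenuation channel-2 amplitude relative to channel 1.
#' @param ch2_noise_factor channel-2 noise multiplier.
#' @param wavelet_dur,wavelet_freq burst duration (s) and centre frequency (Hz).
#' @return an [accel_recording()]; attribute `tap_times` holds the true tap
#'   onsets and `tap_speeds` the wave speed at each tap.
#' @export
render_tap_recording <- function(wave_speed, fs = 50660, spacing = 0.008,
                                 tap_interval = 0.01, noise_scale = 0,
                                 seed = 1L, attenuation = 0.5,
                                 ch2_noise_factor = 2,
                                 wavelet_dur = 0.002, wavelet_freq = 800) {
  if (noise_scale < 0) stop("noise_scale must be non-negative")
  t0 <- wave_speed$time_s[1]
  t_end <- wave_speed$time_s[nrow(wave_speed)]
  taps <- seq(t0, t_end - 2 * wavelet_dur, by = tap_interval)
  speeds <- resample_linear(wave_speed$time_s, wave_speed$speed_mps, taps)
  n <- ceiling((t_end - t0) * fs)
  ch1 <- numeric(n); ch2 <- numeric(n)
  for (k in seq_along(taps)) {
    d <- spacing / speeds[k]
    i0 <- max(1L, floor((taps[k] - t0) * fs) + 1L)
    i1 <- min(n, ceiling((taps[k] - t0 + wavelet_dur + d) * fs) + 2L)
    idx <- i0:i1
    ts <- (idx - 1L) / fs + t0
    ch1[idx] <- ch1[idx] + tap_wavelet_fun(ts - taps[k], wavelet_dur,
                                           wavelet_freq)
    ch2[idx] <- ch2[idx] + attenuation *
      tap_wavelet_fun(ts - taps[k] - d, wavelet_dur, wavelet_freq)
  }
  if (noise_scale > 0) {
    with_seed(seed, {
      ch1 <- ch1 + rnorm(n, 0, noise_scale)
      ch2 <- ch2 + rnorm(n, 0, ch2_noise_factor * noise_scale)
    })
  }
  rec <- accel_recording(ch1, ch2, fs, start_time = t0)
  attr(rec, "tap_times") <- taps
  attr(rec, "tap_speeds") <- speeds
  rec
}

#' Generate a balance-plate sway calibration trial
#'
#' Emulates the calibration protocol: the participant sways
#' anterior-posterior on a balance plate while vertical force and centre of
#' pressure are sampled at 1000 Hz; true ankle moment is
#' `Fz * (COP - ankle axis)`, converted to a true wave-speed stream by
#' inverting the participant's calibration. A sharp manual-impact spike is
#' injected into both the plate force and the wave-speed stream at
#' `impact_time` so the two clocks can be aligned; the wave-speed stream can
#' additionally start `sync_offset` seconds later than the plate clock.
#'
#' @param profile a [participant_profile()].
#' @param duration trial length in s.
#' @param impact_time manual plate-strike time in s (0 < impact_time < duration).
#' @param noise_scale noise amplitude as a fraction of signal amplitude.
#' @param seed integer RNG seed.
#' @param fs plate sample rate in Hz.
#' @param sway_freq anterior-posterior sway frequency in Hz.
#' @param cop_mean,cop_amp mean anterior COP offset from the ankle axis and
#'   sway amplitude, m (kept positive so the tendon stays loaded).
#' @param sync_offset injected start delay of the wave-speed stream, s.
#' @return a `sway_trial` list: `plate` (data.frame `time_s`, `fz_n`,
#'   `cop_ap_m`), `ankle_axis_ap`, `wave_speed` (data.frame on its own,
#'   possibly delayed, clock) and `truth` (calibration coefficients, moment
#'   stream, impact time, injected offset).
#' @export
make_sway_trial <- function(profile, duration = 30, impact_time = 0.35,
                            noise_scale = 0, seed = 1L, fs = 1000,
                            sway_freq = 0.4, cop_mean = 0.06, cop_amp = 0.05,
                            sync_offset = 0) {
  stopifnot(impact_time > 0, impact_time < duration, sync_offset >= 0)
  t <- seq(0, duration, by = 1 / fs)
  g <- 9.81
  fz <- profile$mass * g * (1 + 0.015 * sin(2 * pi * sway_freq * t + pi / 3))
  cop <- cop_mean + cop_amp * sin(2 * pi * sway_freq * t)
  moment <- fz * cop
  speed_true <- sqrt((moment - profile$calib_intercept) / profile$calib_slope)
  # manual strike: short triangular spike on the plate and in the
  # accelerometer-derived stream
  spike <- function(tt, t_imp, width = 0.01) {
    pmax(0, 1 - abs(tt - t_imp) / width)
  }
  fz_spiked <- fz + 0.8 * profile$mass * g * spike(t, impact_time)
  t_ws <- seq(0, duration - sync_offset, by = 1 / fs)
  speed_ws <- resample_linear(t, speed_true, t_ws + sync_offset) +
    25 * spike(t_ws + sync_offset, impact_time)
  cop_obs <- cop
  if (noise_scale > 0) {
    with_seed(seed, {
      fz_spiked <- fz_spiked + rnorm(length(t), 0, noise_scale * mean(fz))
      cop_obs <- cop + rnorm(length(t), 0, noise_scale * cop_amp)
      speed_ws <- speed_ws +
        rnorm(length(t_ws), 0, noise_scale * mean(speed_true))
    })
  }
  structure(list(
    plate = data.frame(time_s = t, fz_n = fz_spiked, cop_ap_m = cop_obs),
    ankle_axis_ap = 0,
    wave_speed = data.frame(time_s = t_ws, speed_mps = speed_ws),
    truth = list(c1 = profile$calib_slope, c0 = profile$calib_intercept,
                 moment = data.frame(time_s = t, moment_nm = moment),
                 impact_time = impact_time, sync_offset = sync_offset)),
    class = "sway_trial")
}

# Fixed power-profile shape: an early negative lobe (energy absorption)
# followed by a larger positive lobe (push-off generation), on u in [0,1].
cohort_power_shape <- function(u) {
  neg <- ifelse(u < 0.3, -0.4 * sin(pi * u / 0.3)^2, 0)
  pos <- ifelse(u >= 0.3, sin(pi * (u - 0.3) / 0.7)^2, 0)
  neg + pos
}

#' Generate a cohort work set with a known slope-to-work law
#'
#' Builds a cohort of synthetic strides whose true per-stride net
#' muscle-tendon work follows a piecewise-linear function of terrain slope
#' with a knot at 0 degrees (separate decline and incline sensitivities per
#' muscle, matching the analysis's separate incline/decline fits), plus a
#' participant-specific level offset and Gaussian stride noise. For each
#' stride and muscle a force (N/kg) and velocity (m/s) sample stream is
#' emitted whose discrete power integral equals the intended work exactly,
#' so the downstream work integrator is exercised end to end.
#'
#' @param n_participants number of participants.
#' @param strides_per strides per participant (>= 1).
#' @param soleus_sens_decline,soleus_sens_incline soleus work sensitivity to
#'   slope on declines / inclines, J/kg per degree.
#' @param gastroc_sens_decline,gastroc_sens_incline gastrocnemius
#'   sensitivities, J/kg per degree.
#' @param work_noise_sd stride-to-stride work noise SD, J/kg.
#' @param seed integer RNG seed.
#' @param n_samples samples per stride stream.
#' @param w_level_soleus,w_level_gastroc cohort-mean level net work, J/kg.
#' @param participant_sd SD of the per-participant level-work offset, J/kg.
#' @param stride_time stride duration, s.
#' @param slopes optional explicit slope vector (length
#'   `n_participants * strides_per`); by default each participant covers
#'   \[-10, 10\] with a jittered, shuffled systematic grid (an even spread
#'   of slopes, as walking an out-and-back hill course produces).
#' @return a `cohort_workset` list: `strides` (data.frame `participant`,
#'   `stride_id`, `slope_deg`), `mechanics` (list per stride with `times`,
#'   `FS`, `VS`, `FG`, `VG`), `truth` (data.frame with intended noise-free
#'   law `w_*_line` and realized target `w_*_target` per stride) and the
#'   configured sensitivities.
#' @export
make_cohort_workset <- function(n_participants = 11, strides_per = 200,
                                soleus_sens_decline = 0.02,
                                soleus_sens_incline = 0.01,
                                gastroc_sens_decline = 0.008,
                                gastroc_sens_incline = -0.008,
                                work_noise_sd = 0.05, seed = 1L,
                                n_samples = 101,
                                w_level_soleus = 0.25, w_level_gastroc = 0.12,
                                participant_sd = 0.05, stride_time = 1.22,
                                slopes = NULL) {
  if (strides_per < 1) stop("strides_per must be positive")
  stopifnot(n_participants >= 1, work_noise_sd >= 0, n_samples >= 3)
  n_total <- n_participants * strides_per
  law <- function(slope, s_dec, s_inc) {
    ifelse(slope <= 0, s_dec * slope, s_inc * slope)
  }
  with_seed(seed, {
    if (is.null(slopes)) {
      # each participant covers the full slope range evenly (as on an
      # out-and-back course), via a jittered, shuffled systematic grid
      grid <- seq(-10, 10, length.out = strides_per)
      step <- if (strides_per > 1) diff(grid[1:2]) else 20
      slopes <- as.vector(vapply(seq_len(n_participants), function(p) {
        s <- grid + runif(strides_per, -step / 2, step / 2)
        sample(pmin(10, pmax(-10, s)))
      }, numeric(strides_per)))
    }
    stopifnot(length(slopes) == n_total)
    off_s <- rnorm(n_participants, 0, participant_sd)
    off_g <- rnorm(n_participants, 0, participant_sd)
    noise_s <- rnorm(n_total, 0, work_noise_sd)
    noise_g <- rnorm(n_total, 0, work_noise_sd)
  })
  part <- rep(sprintf("P%02d", seq_len(n_participants)), each = strides_per)
  pidx <- rep(seq_len(n_participants), each = strides_per)
  ws_line <- w_level_soleus + off_s[pidx] +
    law(slopes, soleus_sens_decline, soleus_sens_incline)
  wg_line <- w_level_gastroc + off_g[pidx] +
    law(slopes, gastroc_sens_decline, gastroc_sens_incline)
  ws_target <- ws_line + noise_s
  wg_target <- wg_line + noise_g
  times <- seq(0, stride_time, length.out = n_samples)
  u <- times / stride_time
  p_shape <- cohort_power_shape(u)
  shape_int <- pracma::trapz(times, p_shape)
  f_sol <- 0.5 + 12 * sin(pi * u)^2   # N/kg, strictly positive
  f_gas <- 0.5 + 6 * sin(pi * u)^2
  mech <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    ps <- ws_target[i] / shape_int * p_shape
    pg <- wg_target[i] / shape_int * p_shape
    mech[[i]] <- list(times = times,
                      FS = f_sol, VS = -ps / f_sol,
                      FG = f_gas, VG = -pg / f_gas)
  }
  structure(list(
    strides = data.frame(participant = part,
                         stride_id = seq_len(n_total), slope_deg = slopes),
    mechanics = mech,
    truth = data.frame(participant = part, stride_id = seq_len(n_total),
                       slope_deg = slopes,
                       w_soleus_line = ws_line, w_gastroc_line = wg_line,
                       w_soleus_target = ws_target,
                       w_gastroc_target = wg_target),
    sensitivities = list(soleus_decline = soleus_sens_decline,
                         soleus_incline = soleus_sens_incline,
                         gastroc_decline = gastroc_sens_decline,
                         gastroc_incline = gastroc_sens_incline),
    work_noise_sd = work_noise_sd, seed = seed),
    class = "cohort_workset")
}

#' Render a heel-strike impact accelerometer trace
#'
#' Low-rate foot-impact signal for exercising heel-strike detection: each
#' heel strike excites a decaying ~25 Hz ringing (inside the 10-50 Hz
#' impact analysis band), plus optional white noise.
#'
#' @param heel_strikes impact times in s.
#' @param fs sample rate in Hz.
#' @param duration trace length in s (default: past the last strike).
#' @param ring_freq ringing frequency in Hz.
#' @param decay exponential decay rate in 1/s.
#' @param noise_sd additive noise SD (signal amplitude is ~1).
#' @param seed integer RNG seed for the noise.
#' @param start_time time of the first sample in s.
#' @return data.frame with `time_s` and `accel`.
#' @export
render_heel_strike_accel <- function(heel_strikes, fs = 100, duration = NULL,
                                     ring_freq = 25, decay = 30,
                                     noise_sd = 0, seed = 1L,
                                     start_time = 0) {
  if (is.null(duration)) duration <- max(heel_strikes) - start_time + 0.5
  t <- seq(start_time, start_time + duration, by = 1 / fs)
  x <- numeric(length(t))
  for (h in heel_strikes) {
    u <- t - h
    m <- u >= 0 & u < 0.3
    x[m] <- x[m] + exp(-decay * u[m]) * sin(2 * pi * ring_freq * u[m])
  }
  if (noise_sd > 0) {
    with_seed(seed, x <- x + rnorm(length(x), 0, noise_sd))
  }
  data.frame(time_s = t, accel = x)
}
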