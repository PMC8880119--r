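test_that("band-pass filtering is linear and zero-phase", {
  fs <- 50660
  n <- 4096
  z <- accel_recording(rep(0, n), rep(0, n), fs)
  expect_equal(bandpass_filter(z)$ch1, rep(0, n))
  set.seed(4)
  x <- rnorm(n)
  r1 <- accel_recording(x, x, fs)
  r2 <- accel_recording(2 * x, 2 * x, fs)
  expect_equal(bandpass_filter(r2)$ch1, 2 * bandpass_filter(r1)$ch1,
               tolerance = 1e-12)
  expect_error(bandpass_filter(r1, low = 150, high = fs), "fs/2")
})

test_that("out-of-band sinusoids are strongly attenuated", {
  fs <- 50660
  t <- (0:49999) / fs
  x <- sin(2 * pi * 15 * t)
  rec <- bandpass_filter(accel_recording(x, x, fs))
  # 15 Hz is a decade below the 150 Hz corner of a 4th-order band-pass
  expect_lt(sqrt(mean(rec$ch1^2)) / sqrt(mean(x^2)), 0.01)
})

test_that("taps are detected at their true times", {
  wst <- data.frame(time_s = seq(0, 1.05, by = 0.01), speed_mps = 35)
  rec <- bandpass_filter(render_tap_recording(wst, noise_scale = 0))
  taps_true <- attr(rec, "tap_times")
  taps <- detect_taps(rec)
  # all interior taps found within +/- 0.1 ms
  interior <- taps_true[taps_true > 0.005 & taps_true < 1.0]
  err <- vapply(interior, function(tt) min(abs(taps - tt)), numeric(1))
  expect_gte(length(taps), length(interior))
  expect_lt(max(err), 1e-4)
})

test_that("pure noise yields no taps and close pairs are merged", {
  set.seed(5)
  noise <- accel_recording(rnorm(60000), rnorm(60000), 50660)
  expect_warning(taps <- detect_taps(noise), "no")
  expect_length(taps, 0)
  # two taps 3 ms apart: only the better-matching one survives min_spacing
  fs <- 50660
  t <- (0:9999) / fs
  x <- tensiowork:::tap_wavelet_fun(t - 0.05, 0.002, 800) +
    tensiowork:::tap_wavelet_fun(t - 0.053, 0.002, 1200)
  rec <- accel_recording(x, x, fs)
  tpl <- tensiowork:::tap_wavelet_fun((0:(round(0.002 * fs) - 1)) / fs,
                                      0.002, 800)
  taps <- detect_taps(rec, template = tpl)
  expect_length(taps, 1)
  expect_equal(taps, 0.05, tolerance = 1e-4)
})

test_that("travel-time estimator handles integer, zero and fractional shifts", {
  fs <- 50660
  w <- wavelet_window(fs)
  # identity
  e0 <- tap_delay(w, w, fs)
  expect_equal(e0$delay_samples, 0)
  expect_equal(e0$quality, 1, tolerance = 1e-9)
  # exact integer shift
  w10 <- c(rep(0, 10), w)[seq_along(w)]
  expect_equal(tap_delay(w, w10, fs)$delay_samples, 10, tolerance = 1e-7)
  # band-limited fractional shift: synthesis is the oracle
  w105 <- fractional_shift(w, 10.5)
  expect_equal(tap_delay(w, w105, fs)$delay_samples, 10.5, tolerance = 0.01)
  # flat windows are flagged invalid
  expect_false(tap_delay(rep(0, 64), rep(0, 64), fs)$valid)
})

test_that("wave speed series reproduces generator truth and flags bad taps", {
  # arithmetic: 160 us delay over 8 mm is 50 m/s
  expect_equal(0.008 / 160e-6, 50)
  wst <- data.frame(time_s = seq(0, 1, by = 0.01), speed_mps = 30)
  rec <- bandpass_filter(render_tap_recording(wst, noise_scale = 0))
  ws <- wave_speed_series(rec)
  expect_s3_class(ws, "wave_speed_series")
  expect_true(all(ws$valid))
  expect_lt(abs(mean(ws$speed_mps) - 30), 0.1)
  expect_true(all(abs(ws$quality) <= 1))
  # swapped channels make every delay negative -> all-invalid error
  swapped <- accel_recording(rec$ch2, rec$ch1, rec$fs)
  expect_error(wave_speed_series(swapped, trial_id = "P99"), "P99")
})

test_that("end-to-end wave speed recovery is within 1% at zero noise", {
  tr <- quick_trial(n_strides = 2)
  rec <- bandpass_filter(render_tap_recording(tr$truth$wave_speed))
  ws <- wave_speed_series(rec)
  truth <- approx(tr$truth$wave_speed$time_s, tr$truth$wave_speed$speed_mps,
                  ws$time_s)$y
  expect_lt(sqrt(mean((ws$speed_mps - truth)^2)) / mean(truth), 0.01)
})

test_that("wave speed CSV round-trips", {
  wst <- data.frame(time_s = seq(0, 0.5, by = 0.01), speed_mps = 40)
  rec <- bandpass_filter(render_tap_recording(wst))
  ws <- wave_speed_series(rec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_wave_speed_csv(ws, path)
  back <- read_wave_speed_csv(path)
  expect_equal(back$speed_mps, ws$speed_mps, tolerance = 1e-9)
  expect_equal(back$valid, ws$valid)
})
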