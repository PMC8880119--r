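test_that("flat course is identically level and non-positive lengths are rejected", {
  crs <- make_course(total_length = 200, max_slope = 0, section_length = 25,
                     seed = 1)
  expect_true(all(crs$map$incline_deg == 0))
  expect_error(make_course(total_length = -5), "positive")
  expect_error(make_course(section_length = 0), "positive")
})

test_that("out-and-back course is odd-symmetric about the turnaround", {
  crs <- make_course(800, 10, 50, seed = 7)
  set.seed(11)
  p <- runif(100, 0, 800)
  expect_equal(course_incline(crs, p), -course_incline(crs, 800 - p),
               tolerance = 1e-9)
})

test_that("an 800 m course with 50 m sections populates every 2-degree bin", {
  crs <- make_course(800, 10, 50, seed = 7)
  bins <- slope_bin(crs$sections$incline_deg)
  expect_true(all(seq(-10, 10, by = 2) %in% bins))
})

test_that("constant moment template maps to the analytic constant wave speed", {
  # oracle: invert M = c1 S^2 + c0 by hand -> S = sqrt((27 + 17) / 0.05)
  tr <- make_trial(default_profile(), gait_pattern_default(moment_template = 27),
                   trial_spec(4, 0, seed = 1))
  expect_equal(tr$truth$wave_speed$speed_mps,
               rep(sqrt((27 + 17) / 0.05), nrow(tr$truth$wave_speed)),
               tolerance = 1e-12)
  expect_equal(sqrt((27 + 17) / 0.05), 29.66479, tolerance = 1e-6)
})

test_that("trials carry the requested stride structure and delay", {
  tr <- quick_trial(n_strides = 10)
  expect_length(tr$truth$heel_strikes, 11)
  expect_equal(max(tr$truth$heel_strikes), 10 * 1.6 / 1.31, tolerance = 1e-9)
  # level stride metrics match the configured profile
  expect_equal(diff(tr$truth$heel_strikes), rep(1.6 / 1.31, 10))
  # delayed tensiometry clock: value at ws-time t equals truth at t + delay
  trd <- quick_trial(n_strides = 10, sync_delay = 0.05)
  tru <- approx(trd$truth$wave_speed$time_s, trd$truth$wave_speed$speed_mps,
                trd$wave_speed$time_s + 0.05)$y
  expect_equal(trd$wave_speed$speed_mps, tru, tolerance = 1e-6)
})

test_that("moments below the calibration floor are rejected with a diagnostic", {
  prof <- participant_profile(calib_intercept = 10)
  expect_error(make_trial(prof, gait_pattern_default(moment_template = 5),
                          trial_spec(2, 0)), "intercept floor")
})

test_that("tap rendering realizes spacing/speed delays and is reproducible", {
  wst <- data.frame(time_s = seq(0, 0.3, by = 0.01), speed_mps = 40)
  rec <- render_tap_recording(wst, noise_scale = 0, seed = 1)
  taps <- attr(rec, "tap_times")
  # delay between channels is spacing / speed = 200 us at every tap
  L <- round(0.004 * rec$fs)
  for (k in c(2, 10, 25)) {
    i0 <- round(taps[k] * rec$fs) + 1L
    est <- tap_delay(rec$ch1[i0:(i0 + L)], rec$ch2[i0:(i0 + L)], rec$fs)
    # within 1% of one sample period of the exact 200 us
    expect_lt(abs(est$delay_s - 0.008 / 40), 0.01 / rec$fs)
  }
  rec2 <- render_tap_recording(wst, noise_scale = 0, seed = 1)
  expect_identical(rec, rec2)
  recn <- render_tap_recording(wst, noise_scale = 1e-4, seed = 3)
  expect_identical(recn,
                   render_tap_recording(wst, noise_scale = 1e-4, seed = 3))
  expect_error(render_tap_recording(wst, noise_scale = -1), "non-negative")
})

test_that("rendered noise level matches the configured amplitude fraction", {
  wst <- data.frame(time_s = seq(0, 0.5, by = 0.01), speed_mps = 40)
  ns <- 3e-5 # 0.003% of the unit wavelet amplitude
  rec <- render_tap_recording(wst, noise_scale = ns, seed = 2)
  rec0 <- render_tap_recording(wst, noise_scale = 0, seed = 2)
  noise1 <- rec$ch1 - rec0$ch1
  noise2 <- rec$ch2 - rec0$ch2
  expect_equal(sd(noise1), ns, tolerance = 0.05)
  expect_gt(sd(noise2), sd(noise1)) # channel 2 noisier
})

test_that("sway trials support exact calibration recovery and spike timing", {
  prof <- default_profile()
  sw <- make_sway_trial(prof, duration = 10, impact_time = 0.35,
                        noise_scale = 0, seed = 1)
  # spike lands at the configured index in the plate stream
  expect_equal(which.max(sw$plate$fz_n), 351)
  # noiseless regression of M on S^2 recovers the truth exactly (away from
  # the spike region)
  away <- abs(sw$plate$time_s - 0.35) > 0.5
  M <- ankle_moment_from_plate(sw$plate, sw$ankle_axis_ap)
  S <- approx(sw$wave_speed$time_s, sw$wave_speed$speed_mps,
              sw$plate$time_s)$y
  fit <- fit_calibration(S[away], M[away])
  expect_equal(fit$c1, prof$calib_slope, tolerance = 1e-6)
  expect_equal(fit$c0, prof$calib_intercept, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("noisy sway trials recover the calibration slope within 5%", {
  prof <- default_profile()
  sw <- make_sway_trial(prof, duration = 30, impact_time = 0.35,
                        noise_scale = 0.01, seed = 3)
  away <- abs(sw$plate$time_s - 0.35) > 0.5
  M <- ankle_moment_from_plate(sw$plate, sw$ankle_axis_ap)
  S <- approx(sw$wave_speed$time_s, sw$wave_speed$speed_mps,
              sw$plate$time_s)$y
  fit <- fit_calibration(S[away], M[away])
  expect_lt(abs(fit$c1 - prof$calib_slope) / prof$calib_slope, 0.05)
})

test_that("cohort work targets follow the configured piecewise law", {
  # degenerate: no noise, no sensitivity, no participant spread
  co0 <- make_cohort_workset(n_participants = 2, strides_per = 25,
                             soleus_sens_decline = 0, soleus_sens_incline = 0,
                             gastroc_sens_decline = 0, gastroc_sens_incline = 0,
                             work_noise_sd = 0, participant_sd = 0, seed = 1)
  expect_equal(var(co0$truth$w_soleus_target), 0, tolerance = 1e-20)
  # single stride at +10 deg: level 0.2 + 0.01 * 10 = 0.3 J/kg, and the
  # emitted streams integrate back to it (trapezoid oracle)
  co1 <- make_cohort_workset(n_participants = 1, strides_per = 1,
                             soleus_sens_incline = 0.01, w_level_soleus = 0.2,
                             work_noise_sd = 0, participant_sd = 0,
                             slopes = 10, seed = 1)
  expect_equal(co1$truth$w_soleus_target, 0.3)
  m <- co1$mechanics[[1]]
  w <- stride_work(mtu_power(m$FS, m$VS), m$times)
  expect_lt(abs(w$net - 0.3), 1e-3)
  # determinism
  expect_identical(make_cohort_workset(seed = 9, n_participants = 2,
                                       strides_per = 30),
                   make_cohort_workset(seed = 9, n_participants = 2,
                                       strides_per = 30))
  expect_error(make_cohort_workset(strides_per = -1), "positive")
})

test_that("calibration round trip is the identity for admissible moments", {
  model <- mean_calibration()
  M <- seq(-15, 120, by = 2.5)
  expect_equal(moment_from_wave_speed(wave_speed_from_moment(M, model), model),
               M, tolerance = 1e-9)
})
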