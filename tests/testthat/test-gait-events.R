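test_that("heel strikes are recovered from synthetic impacts", {
  hs_true <- seq(0.6, 11.4, by = 1.2)
  foot <- render_heel_strike_accel(hs_true, fs = 100, duration = 12,
                                   noise_sd = 0)
  hs <- detect_heel_strikes(foot$accel, 100)
  expect_length(hs, 10)
  expect_lt(max(abs(hs - hs_true)), 0.030)
})

test_that("silence yields no heel strikes and close peaks are suppressed", {
  expect_warning(hs <- detect_heel_strikes(rep(0, 2000), 100), "no heel")
  expect_length(hs, 0)
  # two impact candidates 0.2 s apart: the lower one is suppressed
  f1 <- render_heel_strike_accel(1.0, fs = 100, duration = 3)
  f2 <- render_heel_strike_accel(1.2, fs = 100, duration = 3)
  hs <- detect_heel_strikes(f1$accel + 0.5 * f2$accel, 100)
  expect_length(hs, 1)
  expect_lt(abs(hs - 1.0), 0.030)
})

test_that("stride metrics compute the speed quotient and exclusion rule", {
  t <- seq(0, 5, by = 0.01)
  kin <- data.frame(time_s = t, pelvis_x_m = t * 1.6 / 1.2214)
  st <- stride_metrics(kin, c(0, 1.2214, 2.4428))
  expect_equal(st$stride_length_m, c(1.6, 1.6), tolerance = 1e-9)
  expect_equal(st$speed_mps, c(1.31, 1.31), tolerance = 1e-4)
  expect_true(all(st$included))
  # a 3.5 m stride is omitted
  kin2 <- data.frame(time_s = t, pelvis_x_m = t * 3.5 / 1.2)
  st2 <- stride_metrics(kin2, c(0, 1.2))
  expect_false(st2$included)
  expect_equal(st2$exclusion_reason, "stride_length_gt_3m")
  expect_error(stride_metrics(kin, 1.0), "two heel strikes")
  expect_error(stride_metrics(kin, c(2, 1)), "increasing")
})

test_that("course map construction averages, mirrors and median-filters", {
  d <- seq(0, 400, by = 0.5)
  # constant 5 degree hill: the return pass reads -5 in its own frame
  out <- data.frame(displacement_m = d, incline_deg = rep(5, length(d)))
  back <- data.frame(displacement_m = d, incline_deg = rep(-5, length(d)))
  map <- build_course_map(out, back, known_length = 400)
  expect_equal(map$incline_deg, rep(5, nrow(map)))
  # disagreeing passes average: 4 and 6 -> 5
  out2 <- data.frame(displacement_m = d, incline_deg = rep(4, length(d)))
  back2 <- data.frame(displacement_m = d, incline_deg = rep(-6, length(d)))
  expect_equal(build_course_map(out2, back2, 400)$incline_deg[100], 5)
  # a single-sample +30 degree glitch is removed by the 2 m median
  glitch <- out
  glitch$incline_deg[200] <- 30
  mapg <- build_course_map(glitch, back, 400)
  expect_lt(max(mapg$incline_deg), 5.5)
  # grossly unequal coverage errors
  short <- data.frame(displacement_m = seq(0, 300, 0.5),
                      incline_deg = rep(-5, 601))
  expect_error(build_course_map(out, short, 400), "unequal")
})

test_that("slope binning is nearest-even with ties toward zero", {
  expect_equal(slope_bin(3.2), 4)
  expect_equal(slope_bin(-9.7), -10)
  expect_equal(slope_bin(5.0), 4) # tie between 4 and 6 resolves toward zero
  expect_equal(slope_bin(-5.0), -4)
  expect_equal(slope_bin(1.0), 0)
  expect_equal(slope_bin(0), 0)
  expect_equal(slope_bin(11), 10) # clamped
  # odd symmetry over random slopes
  set.seed(3)
  s <- runif(200, -10, 10)
  expect_equal(slope_bin(-s), -slope_bin(s))
})

test_that("stride slopes come from the map and off-course strides are flagged", {
  crs <- make_course(400, 10, 50, seed = 2)
  t <- seq(0, 40, by = 0.01)
  kin <- data.frame(time_s = t, pelvis_x_m = 1.3 * t)
  st <- stride_metrics(kin, seq(0, 40, by = 1.25))
  st <- assign_and_bin_slope(st, crs)
  expect_true(all(!is.na(st$slope_deg)))
  expect_equal(st$slope_deg,
               course_incline(crs, st$midpoint_x_m), tolerance = 1e-9)
  expect_equal(st$slope_bin, slope_bin(st$slope_deg))
  # push a stride past the course end
  st2 <- stride_metrics(kin, c(0, 1.25))
  st2$midpoint_x_m <- 450
  st2 <- assign_and_bin_slope(st2, crs)
  expect_false(st2$included)
  expect_equal(st2$exclusion_reason, "off_course")
})

test_that("one-way maps fold out-and-back displacements with sign flip", {
  d <- seq(0, 100, by = 0.5)
  out <- data.frame(displacement_m = d, incline_deg = rep(7, length(d)))
  back <- data.frame(displacement_m = d, incline_deg = rep(-7, length(d)))
  map <- build_course_map(out, back, 100)
  kin <- data.frame(time_s = c(0, 100), pelvis_x_m = c(0, 200))
  st <- stride_metrics(kin, c(10, 12, 80, 82))
  st <- assign_and_bin_slope(st, map, displacement_m = c(22, 60, 162))
  expect_equal(st$slope_deg, c(7, 7, -7))
})

test_that("included stride lengths conserve total pelvis displacement", {
  tr <- quick_trial(n_strides = 8, slope = c(-3, 0, 2, 5, -1, 0, 4, 1))
  st <- stride_metrics(tr$kinematics, tr$truth$heel_strikes)
  total <- diff(range(tr$kinematics$pelvis_x_m))
  expect_equal(sum(st$stride_length_m[st$included]), total, tolerance = 1e-6)
})
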