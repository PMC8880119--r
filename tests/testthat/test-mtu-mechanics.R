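test_that("moment arms evaluate the quadratic models", {
  R <- moment_arms(0, 0)
  expect_equal(R$ankle, 0.044)
  expect_equal(R$knee, 0.018)
  expect_equal(moment_arms(10, 0)$ankle,
               1.4e-6 * 100 - 1.7e-4 * 10 + 4.4e-2)
  expect_equal(moment_arms(0, 20)$knee,
               -2.0e-6 * 400 + 3.8e-4 * 20 + 1.8e-2)
})

test_that("MTU velocities follow the moment-arm kinematics", {
  v <- mtu_velocities(0, 1, 0, 0)
  expect_equal(v$VS, 0.044)
  expect_equal(v$VG, 0.044)
  v2 <- mtu_velocities(0, 0, 0, 1)
  expect_equal(v2$VS, 0)
  expect_equal(v2$VG, -0.018)
  v3 <- mtu_velocities(5, 0, 30, 0)
  expect_equal(v3$VS, 0)
  expect_equal(v3$VG, 0)
})

test_that("excursions vanish at neutral and integrate the moment arms", {
  e0 <- mtu_excursions(0, 0)
  expect_equal(e0$soleus, 0)
  expect_equal(e0$gastroc, 0)
  # derivative of excursion wrt ankle angle (in rad) equals the moment arm
  th <- seq(-20, 20, by = 0.5)
  h <- 1e-4
  dd <- (mtu_excursions(th + h)$soleus - mtu_excursions(th - h)$soleus) /
    (2 * h * pi / 180)
  expect_lt(max(abs(dd - moment_arms(th)$ankle)), 1e-6)
  # numeric quadrature oracle at theta = 10 deg
  oracle <- integrate(function(x) moment_arms(x)$ankle * pi / 180, 0, 10,
                      rel.tol = 1e-10)$value
  expect_equal(mtu_excursions(10)$soleus, oracle, tolerance = 1e-8)
  expect_equal(oracle, 0.00754, tolerance = 1e-3)
  # biarticular reduction: knee at neutral makes gastroc equal soleus
  eg <- mtu_excursions(th, 0)
  expect_equal(eg$gastroc, eg$soleus)
})

test_that("force apportionment is conservative and clips compression", {
  f <- tendon_force_and_apportion(44, 0, mass = 80)
  expect_equal(f$F, 1000)
  expect_equal(f$FS, 0.65 * 1000 / 80)
  expect_equal(f$FG, 0.35 * 1000 / 80)
  expect_equal(f$FS, 8.125)
  expect_equal(f$FG, 4.375)
  # FS + FG = F/m exactly, for arbitrary streams
  set.seed(6)
  M <- runif(200, -10, 90)
  th <- runif(200, -20, 15)
  fa <- tendon_force_and_apportion(M, th, mass = 76.5)
  expect_equal(fa$FS + fa$FG, fa$F / 76.5, tolerance = 1e-12)
  expect_equal(fa$n_clipped, sum(M < 0))
  expect_true(all(fa$F >= 0))
  z <- tendon_force_and_apportion(0, 0, mass = 80)
  expect_equal(c(z$F, z$FS, z$FG), c(0, 0, 0))
})

test_that("power sign convention rewards shortening under tension", {
  expect_equal(mtu_power(10, -0.1), 1.0)
  expect_equal(mtu_power(5, 0.2), -1.0)
  expect_equal(mtu_power(7, 0), 0)
})

test_that("stride work splits into consistent positive and negative parts", {
  t <- seq(0, 1, by = 0.01)
  w <- stride_work(rep(1, length(t)), t)
  expect_equal(c(w$net, w$pos, w$neg), c(1, 1, 0))
  ws <- stride_work(sin(2 * pi * t), t)
  expect_equal(ws$net, 0, tolerance = 1e-12)
  expect_equal(ws$pos, -ws$neg, tolerance = 1e-12)
  expect_error(stride_work(rep(1, 3), c(0, 2, 1)), "increasing")
  # discretization against a 100x finer grid oracle
  tf <- seq(0, 1, length.out = 10001)
  p <- function(x) sin(2 * pi * x)^2 * cos(3 * x)
  expect_lt(abs(stride_work(p(t), t)$net - pracma::trapz(tf, p(tf))), 1e-3)
  # net = pos + neg across random power profiles
  set.seed(7)
  for (i in 1:10) {
    P <- rnorm(101)
    w <- stride_work(P, seq(0, 1.2, length.out = 101))
    expect_equal(w$net, w$pos + w$neg, tolerance = 1e-9)
  }
})

test_that("work against gravity follows the half-rise formula", {
  expect_equal(work_against_gravity(1.6, 0), 0)
  expect_equal(work_against_gravity(1.6, 10),
               0.5 * 9.81 * 1.6 * tan(10 * pi / 180))
  expect_equal(work_against_gravity(1.6, 10), 1.3839, tolerance = 1e-4)
  s <- seq(-10, 10, by = 2.5)
  expect_equal(work_against_gravity(1.5, -s), -work_against_gravity(1.5, s))
})

test_that("work-loop area equals time-integrated net work", {
  # synthetic stride: force and velocity streams, excursion = integral of V
  t <- seq(0, 1.2, length.out = 241)
  F <- 0.5 + 8 * sin(pi * t / 1.2)^2
  V <- 0.05 * sin(2 * pi * t / 1.2) - 0.02 * sin(4 * pi * t / 1.2 + 0.7)
  L <- pracma::cumtrapz(t, V)[, 1]
  wl <- work_loop(F, L)
  net <- stride_work(mtu_power(F, V), t)$net
  expect_lt(abs(wl$area - net), 1e-3)
  # zero force: no area
  expect_equal(work_loop(rep(0, 100), seq(0, 1, length.out = 100))$area, 0)
  # reversing the path flips the sign
  expect_equal(work_loop(rev(F), rev(L))$area, -wl$area, tolerance = 1e-12)
  expect_error(work_loop(1:2, 1:2), "3 samples")
})

test_that("per-stride mechanics assembly is internally consistent", {
  tr <- quick_trial(n_strides = 3)
  kin <- tr$kinematics
  hs <- tr$truth$heel_strikes
  sel <- kin$time_s >= hs[2] & kin$time_s <= hs[3]
  m <- mtu_stride_mechanics(kin$time_s[sel], kin$ankle_deg[sel],
                            kin$knee_deg[sel],
                            tr$truth$wave_speed$speed_mps[sel],
                            mean_calibration(), mass = 76.5)
  st <- m$streams
  expect_equal(m$work$soleus$net, m$work$soleus$pos + m$work$soleus$neg,
               tolerance = 1e-9)
  # power columns match the force/velocity products
  expect_equal(st$PS_Wkg, -st$VS * st$FS_Nkg)
  expect_equal(st$PG_Wkg, -st$VG * st$FG_Nkg)
  # loop area agrees with integrated net work on this stride
  wl <- work_loop(st$FS_Nkg, st$excS_m)
  expect_lt(abs(wl$area - m$work$soleus$net), 2e-3)
})
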