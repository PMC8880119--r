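# Muscle-tendon unit (MTU) mechanics for the triceps surae. Joint-angle
# dependent moment arms convert joint rotation to MTU velocity and
# excursion; the calibrated ankle moment converts to total Achilles force,
# apportioned to soleus/gastrocnemius by physiological cross-sectional
# area; power is the negative product of force and lengthening velocity,
# and stride work its time integral (net, positive, negative). Work loops
# (force vs excursion) close the stride path and report shoelace area.

#' Moment-arm model
#'
#' Quadratic fits of the Achilles moment arm about the ankle
#' (`R_ankle(theta) = a2 theta^2 + a1 theta + a0`, dorsiflexion `theta` in
#' degrees, arm in m) and of the proximal gastrocnemius tendon moment arm
#' about the knee (`R_knee(phi)`, knee flexion `phi` in degrees). Defaults
#' are generic healthy-adult fits: at neutral standing the arms are 0.044 m
#' (ankle) and 0.018 m (knee).
#'
#' @param ankle_coeffs quadratic coefficients `(a2, a1, a0)` in degrees to m.
#' @param knee_coeffs quadratic coefficients `(b2, b1, b0)` in degrees to m.
#' @return a `moment_arm_model` list.
#' @export
moment_arm_model <- function(ankle_coeffs = c(1.4e-6, -1.7e-4, 4.4e-2),
                             knee_coeffs = c(-2.0e-6, 3.8e-4, 1.8e-2)) {
  stopifnot(length(ankle_coeffs) == 3, length(knee_coeffs) == 3)
  structure(list(ankle_coeffs = ankle_coeffs, knee_coeffs = knee_coeffs),
            class = "moment_arm_model")
}

#' Evaluate moment arms at joint angles
#'
#' @param theta_deg ankle dorsiflexion in degrees.
#' @param phi_deg knee flexion in degrees.
#' @param model a [moment_arm_model()].
#' @return list with `ankle` and `knee` moment arms in m.
#' @export
moment_arms <- function(theta_deg, phi_deg = 0, model = moment_arm_model()) {
  a <- model$ankle_coeffs; b <- model$knee_coeffs
  list(ankle = a[1] * theta_deg^2 + a[2] * theta_deg + a[3],
       knee = b[1] * phi_deg^2 + b[2] * phi_deg + b[3])
}

#' MTU lengthening velocities
#'
#' Soleus velocity is the ankle term alone; the biarticular gastrocnemius
#' adds the knee term: `VS = R_ankle(theta) * theta_dot`,
#' `VG = VS - R_knee(phi) * phi_dot`. Angular rates must be in rad/s (the
#' moment-arm polynomials take degrees, but a velocity in m/s requires the
#' rate in rad/s; positive = MTU lengthening).
#'
#' @param theta_deg,phi_deg joint angles in degrees.
#' @param theta_dot,phi_dot joint angular velocities in rad/s.
#' @param model a [moment_arm_model()].
#' @return list with `VS` and `VG` in m/s.
#' @export
mtu_velocities <- function(theta_deg, theta_dot, phi_deg = 0, phi_dot = 0,
                           model = moment_arm_model()) {
  R <- moment_arms(theta_deg, phi_deg, model)
  VS <- R$ankle * theta_dot
  list(VS = VS, VG = VS - R$knee * phi_dot)
}

#' MTU excursions from the neutral pose
#'
#' Symbolic integrals of the moment-arm polynomials with respect to joint
#' angle give the MTU length change relative to upright standing; the
#' pi/180 factor converts the degree-valued integration variable to
#' radians so the excursion is in m:
#' `dL_ankle(theta) = (pi/180) (a2 theta^3/3 + a1 theta^2/2 + a0 theta)`;
#' soleus excursion is the ankle term, gastrocnemius subtracts the knee
#' integral.
#'
#' @param theta_deg,phi_deg joint angles in degrees.
#' @param model a [moment_arm_model()].
#' @return list with `soleus` and `gastroc` excursions in m (0 at neutral).
#' @export
mtu_excursions <- function(theta_deg, phi_deg = 0, model = moment_arm_model()) {
  a <- model$ankle_coeffs; b <- model$knee_coeffs
  k <- pi / 180
  dl_ankle <- k * (a[1] * theta_deg^3 / 3 + a[2] * theta_deg^2 / 2 +
                     a[3] * theta_deg)
  dl_knee <- k * (b[1] * phi_deg^3 / 3 + b[2] * phi_deg^2 / 2 +
                    b[3] * phi_deg)
  list(soleus = dl_ankle, gastroc = dl_ankle - dl_knee)
}

#' Joint angular velocity from a sampled angle stream
#'
#' Low-pass filters the angle stream (zero-phase Butterworth, default 6 Hz)
#' and differentiates by central differences, returning rad/s.
#'
#' @param angle_deg angle samples in degrees.
#' @param fs sample rate in Hz.
#' @param cutoff low-pass cutoff in Hz; `NA` disables smoothing.
#' @param order overall filter order.
#' @return angular velocity in rad/s.
#' @export
angular_velocity <- function(angle_deg, fs, cutoff = 6, order = 4) {
  pracma::gradient(lowpass_angle(angle_deg, fs, cutoff, order), 1 / fs) *
    pi / 180
}

# zero-phase low-pass of an angle stream (no-op for short streams)
lowpass_angle <- function(angle_deg, fs, cutoff = 6, order = 4) {
  if (is.finite(cutoff) && length(angle_deg) > 6L * order && cutoff < fs / 2) {
    bf <- signal::butter(order / 2, cutoff / (fs / 2), type = "low")
    as.numeric(signal::filtfilt(bf, angle_deg))
  } else angle_deg
}

#' Total Achilles force and soleus/gastrocnemius apportionment
#'
#' Total tendon force is `F = M / R_ankle(theta)`; negative moments are
#' clipped to zero (a tendon transmits tension only; the clip count is
#' reported). The force is split by physiological cross-sectional area:
#' 65% soleus, 35% gastrocnemius, normalized to body mass.
#'
#' @param M net ankle moment in N m.
#' @param theta_deg ankle dorsiflexion in degrees.
#' @param mass body mass in kg (> 0).
#' @param soleus_frac soleus share of total force.
#' @param model a [moment_arm_model()].
#' @return list with `F` (N), `FS`, `FG` (N/kg) and `n_clipped`.
#' @export
tendon_force_and_apportion <- function(M, theta_deg, mass,
                                       soleus_frac = 0.65,
                                       model = moment_arm_model()) {
  stopifnot(mass > 0, soleus_frac >= 0, soleus_frac <= 1)
  R <- moment_arms(theta_deg, 0, model)$ankle
  if (any(R <= 0)) stop("ankle moment arm must be positive")
  n_clipped <- sum(M < 0, na.rm = TRUE)
  Mc <- pmax(M, 0)
  F <- Mc / R
  list(F = F, FS = soleus_frac * F / mass, FG = (1 - soleus_frac) * F / mass,
       n_clipped = n_clipped)
}

#' Instantaneous MTU power
#'
#' `P = -V * F`: shortening (negative velocity) under tension produces
#' positive power.
#'
#' @param F_muscle muscle force in N/kg.
#' @param V_muscle lengthening velocity in m/s.
#' @return power in W/kg.
#' @export
mtu_power <- function(F_muscle, V_muscle) -V_muscle * F_muscle

#' Net, positive and negative stride work
#'
#' Trapezoidal integration of the power stream over the stride; positive
#' work integrates `max(P, 0)`, negative work `min(P, 0)`, so
#' `net = pos + neg` to machine precision.
#'
#' @param P power stream in W/kg.
#' @param times sample times in s (strictly increasing).
#' @return list with `net`, `pos`, `neg` in J/kg.
#' @export
stride_work <- function(P, times) {
  stopifnot(length(P) == length(times), length(P) >= 2)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  list(net = pracma::trapz(times, P),
       pos = pracma::trapz(times, pmax(P, 0)),
       neg = pracma::trapz(times, pmin(P, 0)))
}

#' Mass-normalized work against gravity per stride
#'
#' Half the product of gravitational acceleration, stride length and the
#' tangent of the terrain incline: the potential-energy change of one step
#' (half a stride's rise), per kg of body mass.
#'
#' @param stride_length stride length in m.
#' @param slope_deg terrain incline in degrees (|slope| < 90).
#' @param g gravitational acceleration, m/s^2.
#' @return work in J/kg (negative on declines).
#' @export
work_against_gravity <- function(stride_length, slope_deg, g = 9.81) {
  stopifnot(all(abs(slope_deg) < 90))
  0.5 * g * stride_length * tan(slope_deg * pi / 180)
}

#' Work loop: force-excursion path and shoelace area
#'
#' Orders the force-excursion samples to begin at heel strike, closes the
#' path back to its start, and returns the signed shoelace area. A
#' counter-clockwise loop (in the excursion-force plane) encloses positive
#' area, which equals the net work of the stride.
#'
#' @param force force stream in N/kg.
#' @param excursion excursion stream in m (same length).
#' @param heel_strike_index sample index at which the loop begins.
#' @return list with `path` (data.frame `excursion_m`, `force_nkg`, closed)
#'   and `area` (J/kg).
#' @export
work_loop <- function(force, excursion, heel_strike_index = 1L) {
  stopifnot(length(force) == length(excursion))
  n <- length(force)
  if (n < 3) stop("work loop needs at least 3 samples")
  ord <- c(heel_strike_index:n,
           if (heel_strike_index > 1L) 1:(heel_strike_index - 1L))
  x <- excursion[ord]; y <- force[ord]
  x <- c(x, x[1]); y <- c(y, y[1])
  area <- 0.5 * sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])
  list(path = data.frame(excursion_m = x, force_nkg = y), area = area)
}

#' Per-stride MTU mechanics from calibrated wave speed and kinematics
#'
#' Convenience assembly of the full per-stride chain: angular velocities
#' from the angle streams, moment arms, MTU velocities and excursions,
#' ankle moment from calibrated wave speed, force apportionment, powers,
#' and net/positive/negative work per muscle.
#'
#' @param times sample times in s.
#' @param ankle_deg,knee_deg joint angle streams in degrees.
#' @param speed_mps Achilles wave-speed stream, m/s.
#' @param calibration a [calibration_model()].
#' @param mass body mass in kg.
#' @param model a [moment_arm_model()].
#' @param soleus_frac soleus share of Achilles force.
#' @param fs sample rate (default from `times`).
#' @return an `mtu_stride_mechanics` list: `streams` (data.frame `time_s`,
#'   `VS`, `VG`, `excS_m`, `excG_m`, `FS_Nkg`, `FG_Nkg`, `PS_Wkg`,
#'   `PG_Wkg`) and `work` (per-muscle net/pos/neg, J/kg).
#' @export
mtu_stride_mechanics <- function(times, ankle_deg, knee_deg, speed_mps,
                                 calibration = mean_calibration(), mass,
                                 model = moment_arm_model(),
                                 soleus_frac = 0.65, fs = NULL) {
  stopifnot(length(times) == length(ankle_deg),
            length(times) == length(knee_deg),
            length(times) == length(speed_mps))
  if (is.null(fs)) fs <- 1 / median(diff(times))
  # one smoothed angle stream feeds velocities, excursions and moment arms,
  # keeping the loop area consistent with the time-integrated work
  th <- lowpass_angle(ankle_deg, fs)
  ph <- lowpass_angle(knee_deg, fs)
  th_dot <- pracma::gradient(th, 1 / fs) * pi / 180
  ph_dot <- pracma::gradient(ph, 1 / fs) * pi / 180
  V <- mtu_velocities(th, th_dot, ph, ph_dot, model)
  exc <- mtu_excursions(th, ph, model)
  M <- moment_from_wave_speed(pmax(speed_mps, 0), calibration)
  Fap <- tendon_force_and_apportion(M, th, mass, soleus_frac, model)
  PS <- mtu_power(Fap$FS, V$VS)
  PG <- mtu_power(Fap$FG, V$VG)
  structure(list(
    streams = data.frame(time_s = times, VS = V$VS, VG = V$VG,
                         excS_m = exc$soleus, excG_m = exc$gastroc,
                         FS_Nkg = Fap$FS, FG_Nkg = Fap$FG,
                         PS_Wkg = PS, PG_Wkg = PG),
    work = list(soleus = stride_work(PS, times),
                gastroc = stride_work(PG, times)),
    n_clipped = Fap$n_clipped), class = "mtu_stride_mechanics")
}
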