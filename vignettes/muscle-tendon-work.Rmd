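---
title: "Estimating triceps surae work from wearable tensiometry and IMU kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating triceps surae work from wearable tensiometry and IMU kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensiowork)
```

## The measurement problem

Muscle work is classically measured with the work loop: plot muscle force
against muscle length over a movement cycle and read the enclosed area.
Outside the laboratory neither quantity is directly observable. This
package combines two wearable surrogates for the triceps surae (soleus +
gastrocnemius) during walking:

* **Tendon load** from shear wave tensiometry. A piezoelectric tapper
  excites micrometre-scale shear waves in the Achilles tendon; two
  accelerometers 8 mm apart record their passage. Tension stiffens the
  tendon transversely, so wave speed rises with load; a tensioned-beam
  model predicts tension proportional to squared wave speed, motivating a
  linear calibration from squared speed to net ankle moment.
* **Muscle–tendon length change** from joint kinematics. Quadratic
  moment-arm models of the Achilles about the ankle and of the proximal
  gastrocnemius tendon about the knee convert joint angles and angular
  velocities into muscle–tendon unit (MTU) excursion and velocity.

The product of apportioned force and lengthening velocity (negated, so
shortening under tension is positive) is MTU power; its stride integral is
work; and separate incline/decline regressions of zero-referenced net work
on terrain slope summarize how each muscle's output scales with grade.

Key modelling assumptions, inherited from the measurement approach:

* force is equal in muscle and tendon (series arrangement), and muscle vs
  tendon length change is *not* separated — all quantities are MTU-level;
* total Achilles force splits in a fixed 65%/35% soleus/gastrocnemius
  ratio, the physiological cross-sectional area proportion, ignoring
  activation-dependent or posture-dependent redistribution;
* moment arms follow generic healthy-adult polynomials rather than
  participant-specific imaging;
* the tendon transmits tension only: negative calibrated moments are
  clipped to zero force (the clip count is reported).

## Processing chain and parameter choices

1. **Band-pass filtering** (`bandpass_filter()`): 150–1500 Hz, 4th-order
   Butterworth, applied forward–backward. Zero-phase filtering is a
   deliberate choice for offline analysis — it preserves tap timing, on
   which everything downstream rests.
2. **Tap detection** (`detect_taps()`): normalized cross-correlation of a
   representative tap against channel 1, peaks at least 5 ms apart. The
   representative tap is the highest-energy 2 ms segment of the channel
   (`template = "auto"`); self-extraction avoids shipping a reference
   waveform, and is guarded by an
   energy-contrast check that returns no events on impulse-free streams.
3. **Travel time** (`tap_delay()`): over the 4 ms window anchored at each
   tap (same window on both channels), the integer-lag argmax of the
   normalized cross-correlation is refined by fitting a cosine through the
   peak and its neighbours. The cosine fit (not parabolic) is the estimator's
   subsample interpolator; on noiseless band-limited fractional
   shifts the estimator's error is below 0.01% of the 19.7 µs sample
   period (the test suite enforces < 1%). The mean subtraction is skipped
   for these band-passed windows: a residual DC term breaks the symmetry
   of the correlation about its peak and visibly biases the refinement.
4. **Wave speed** (`wave_speed_series()`): `spacing / delay` per tap, with
   validity flags. Defaults `quality_floor = 0.5` (peak correlation) and
   `speed_bounds = c(2, 150)` m/s are engineering judgement — the field
   method flags "poor signal quality" without naming thresholds — and are
   config-exposed. Invalid taps are linearly interpolated for continuity
   but keep their flags; an all-invalid trial raises an error naming the
   trial, mirroring how a participant with inadequate sensor contact must
   be excluded rather than silently processed.
5. **Calibration** (`fit_calibration()`): during quiet anterior–posterior
   swaying on a balance plate, net ankle moment is vertical force times
   the COP lever arm about the ankle axis (shear force is unavailable in
   this protocol, so the lever-arm product is the whole model). Plate and
   tensiometry clocks are aligned on a manual strike spike; the spike is
   found in the residual from a 25 ms running median (a slowly varying
   sway signal has near-zero residual MAD, hence the scale floor at 5% of
   the stream SD). Moment is regressed on squared speed over raw paired
   samples resampled to 1000 Hz; cycle-averaged pairing would also be
   defensible, but raw pairing uses all the data.
   Repeating the sway trial at session end feeds
   `compare_calibrations()`, whose 15% drift threshold is likewise an
   exposed invention.
6. **Stride segmentation** (`detect_heel_strikes()`): peaks of the
   10–50 Hz band-passed accelerometer, at least 0.4 s apart, above
   2 × MAD of the filtered stream *and* 30% of its largest excursion —
   impact bursts are sparse, so the MAD alone underestimates the noise
   floor between strides. The heel-strike source is the tensiometer's
   distal accelerometer by default (config-selectable). Strides longer than 3 m are
   excluded (`stride_length_gt_3m`): lengths beyond 3 m indicate IMU
   reconstruction errors, not gait.
7. **Slope assignment** (`build_course_map()`, `assign_and_bin_slope()`):
   the course map rescales two mapping passes to the known course length,
   mirrors the return pass with sign flipped, averages, and applies a
   2 m moving median. Stride slope is read at the stride's *midpoint*
   cumulative pelvis displacement (the midpoint is the natural centre of
   the stride), then binned to even-degree centres with ties resolved toward zero so
   boundary strides do not inflate the extreme bins.
8. **Clock alignment** (`estimate_sync_offset()`): the wireless start
   trigger delays the tensiometry stream by 10–100 ms. Per level stride
   (|slope| < 1°, the half-width of the 0° bin), the wave-speed curve
   over the first 10% of the gait cycle is cross-correlated against ankle
   angle, both z-scored so the correlation is amplitude-free, over lags
   within ±150 ms (the delay bound plus margin); the mean lag is applied to the
   whole trial. Angle, not its derivative, is correlated.
9. **Mechanics and statistics** (`mtu_stride_mechanics()`,
   `fit_slope_sensitivity()`): angular velocities come from central
   differences after a 6 Hz zero-phase low-pass (6 Hz sits comfortably
   above voluntary movement content at the 100 Hz kinematic rate). One smoothed angle stream feeds
   velocities, excursions and moment arms so that the work-loop area and
   the time-integrated work agree to discretization error. Work is
   integrated over the full stride, and positive/negative work integrate
   the rectified power parts, so `net = pos + neg` holds identically.
   Strides are pooled across participants after zero-referencing (no
   mixed-effects model: strides are the units of analysis), fit separately
   for declines and inclines at α = 0.05, with 0° strides entering both
   segments: symmetric inclusion avoids favouring either side of the
   boundary (config-exposed via `include_boundary`).

### Units in the velocity equations

The moment-arm polynomials take angles in degrees, but a moment arm in
metres times an angular rate gives m/s only if the rate is in rad/s. The
package therefore takes `θ̇`, `Φ̇` in rad/s everywhere, and the symbolic
excursion integrals carry a π/180 factor converting the degree-valued
integration variable. This is the only dimensionally consistent reading
and is asserted by the test that the excursion derivative reproduces the
moment arm.

## The synthetic generator

Every input the pipeline consumes can be generated with retained truth:

* `make_course()` — an out-and-back course (default 800 m, ±10°) built
  from constant-incline sections whose targets cycle through the 2° bin
  magnitudes with sub-bin jitter, smoothed at section joins; the return
  half mirrors the outward half with sign flipped.
* `make_trial()` — periodic cosine-segment templates of ankle angle, knee
  angle and ankle moment versus gait-cycle fraction, modulated by slope
  (moment peak +3%/°, stance ankle shift +0.25°/°, knee flexion rising
  with |slope|, stride length +0.75%/° at constant speed — level defaults
  1.60 m and 1.31 m/s, the cohort means the generator emulates). True
  moment inverts the participant's calibration into true wave speed; the
  tensiometry stream is emitted on a clock that starts `sync_delay`
  later. Two template features are deliberate: the moment peak falls just
  after the ankle-angle peak, so the force–excursion loop encloses
  positive area, as push-off mechanics require; and both templates share
  a loading-response bump symmetric about 5% of the cycle, because a
  symmetric feature stays symmetric under any monotone transform (such as
  the square-root calibration inverse), making the level-stride
  cross-correlation aligner unbiased by construction rather than by
  accident of shape.
* `render_tap_recording()` — 2 ms raised-cosine tone bursts at 800 Hz
  (inside the 150–1500 Hz analysis band) at each tap on channel 1;
  channel 2 delayed by `spacing/S` via exact evaluation of the continuous
  wavelet at shifted sample times, attenuated 0.5×, with channel-2 noise
  doubled. The burst's spectral content is an assumption — the hardware's
  actual wavelet is undocumented — which is why the subsample-delay tests
  also use generic band-limited shifts (`fractional_shift()`).
* `make_sway_trial()` — 0.4 Hz anterior–posterior COP oscillation kept
  anterior of the ankle axis (so the tendon stays loaded and the
  square-root inversion is defined), with a manual-strike spike injected
  into both streams.
* `make_cohort_workset()` — per-stride force/velocity streams whose
  discrete power integral equals exactly a configured piecewise-linear
  work law (knot at 0°, separate decline/incline sensitivities per
  muscle) plus participant offsets and stride noise. Each participant's
  slopes form a jittered, shuffled systematic grid over ±10° — the even
  coverage an out-and-back hill course produces — rather than an i.i.d.
  draw, which also equalizes slope support across participants.

What the generator does **not** emulate: whole-body dynamics (templates
are phenomenological, not simulated), soft-tissue artefact, sensor
drift/detachment, gait variability beyond white measurement noise, the
crosswalk gap of a real course, or muscle–tendon interaction dynamics.
Passing tests therefore demonstrate that the *processing* recovers known
ground truth under realistic sampling, noise and clock conditions — not
that the biomechanical model is correct for any particular human.

## Numerical choices and degenerate inputs

* Cosine peak interpolation falls back to parabolic when the three-point
  cosine fit is degenerate, and to the integer lag when both are.
* Flat correlation windows are flagged invalid, not errors; streams with
  no impulsive content produce warnings and empty results; spike-free
  alignment, missing level strides, all-invalid trials and degenerate
  (constant-speed) calibration designs raise informative errors.
* Binning ties resolve toward zero; bins are clamped to ±10°.
* `fractional_shift()` keeps the Nyquist bin real; callers pad signals
  whose support approaches the ends (circular shift).
* All generator functions take explicit seeds and save/restore the global
  RNG state, so fixed seeds give byte-identical outputs and library calls
  do not perturb user randomness. The pipeline derives per-stage,
  per-participant substreams from one root seed.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path with comfortable statistical power: tap-level
recordings of a few seconds at the full 50.66 kHz rate; 10–20-stride
trials at 100 Hz kinematics for sync and segmentation checks; 20 trials
for the injected-delay study; and an 11-participant × 200-stride cohort
for the sensitivity regressions (n = 1100 per segment puts the fit's
standard error near 0.0005 J/kg/°, an order of magnitude below the
sensitivities being recovered). The demo pipeline (2 participants ×
120 strides) completes in a few seconds.

## Known limitations

* The 65/35 force split and generic moment arms make absolute work values
  participant-generic; relative trends across slopes are the robust
  output, as with the wearable method itself.
* Work estimates are sensitive to residual clock misalignment (of order
  20% per 1% gait-cycle offset); the sync correction reduces residuals to
  well under 0.1% of the gait cycle on synthetic data, but that figure
  reflects the generator's idealized waveform pair.
* The fast pipeline mode synthesizes wave speed directly at the kinematic
  rate; the full tap-level signal path is exercised on short trials
  (`mode = "full"`), not on long cohort runs.
* `bin_average_curves()` omits empty bins with a warning rather than
  interpolating them.
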