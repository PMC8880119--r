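# Shared fixtures built in code: default participant, a tap-wavelet window
# builder, and a quick trial constructor.

default_profile <- function(...) participant_profile(...)

# 4 ms window at the tensiometer rate containing one tap wavelet
wavelet_window <- function(fs = 50660, window = 0.004, onset = 0.0005,
                           freq = 800) {
  t <- (0:(round(window * fs) - 1)) / fs
  tensiowork:::tap_wavelet_fun(t - onset, dur = 0.002, freq = freq)
}

quick_trial <- function(n_strides = 10, slope = 0, sync_delay = 0,
                        noise = 0, seed = 1, profile = default_profile()) {
  make_trial(profile, gait_pattern_default(),
             trial_spec(n_strides, slope, sync_delay = sync_delay,
                        noise_scale = noise, seed = seed))
}
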