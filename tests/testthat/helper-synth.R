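# Shared fixtures: small synthetic motions built in code.

# default two-center study motion (unit amplitude channels, 120 Hz)
study_motion <- function(seed = 42, noise_sd = 0, markers = 1L,
                         freqs_hz = c(0.5, 1.3), n_m = 25L, duration = 10) {
  synth_motion(synth_spec(n = length(freqs_hz), freqs_hz = freqs_hz,
                          n_m = n_m, markers = markers, duration = duration,
                          noise_sd = noise_sd, seed = seed))
}

# quick short motion for cheap unit tests (K = 360 by default)
short_motion <- function(seed = 1, freqs_hz = c(0.5, 1.3), n_m = 15L,
                         duration = 3, ...) {
  study_motion(seed = seed, freqs_hz = freqs_hz, n_m = n_m,
               duration = duration, ...)
}

grid_step_match <- function(found_hz, true_hz, step = 0.01) {
  all(abs(sort(found_hz) - sort(true_hz)) <= step + 1e-9)
}
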