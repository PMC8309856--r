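# shared fixture builders (all data generated in code)

default_cfg <- radar_config()

# quick noiseless simulation for structural tests
quiet_frames <- function(rate = 15, duration = 10, seed = 1, ...) {
  simulate_frames(
    chest_motion(breathing_rate = rate, noise_sd = 0, rx_noise_sd = 0,
                 heart_amplitude = 0, seed = seed, ...),
    default_cfg, duration)
}

# an auc_series tibble holding an arbitrary sampled signal
make_series <- function(values, frame_rate = 20) {
  respirad:::new_auc_series(values, frame_rate = frame_rate)
}

tone_series <- function(freq_hz, duration = 60, frame_rate = 20,
                        amplitude = 1, phase = 0, offset = 0) {
  t <- (seq_len(round(duration * frame_rate)) - 1) / frame_rate
  make_series(offset + amplitude * sin(2 * pi * freq_hz * t + phase),
              frame_rate = frame_rate)
}

# amplitude of the component at a known frequency, from the central 60%
# (avoids boundary transients); independent of the package's spectrum code
fitted_tone_amplitude <- function(values, freq_hz, frame_rate = 20) {
  n <- length(values)
  idx <- floor(n * 0.2):ceiling(n * 0.8)
  t <- (idx - 1) / frame_rate
  co <- stats::coef(stats::lm(values[idx] ~ sin(2 * pi * freq_hz * t) +
                                cos(2 * pi * freq_hz * t)))
  unname(sqrt(co[2]^2 + co[3]^2))
}
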