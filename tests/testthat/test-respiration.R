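test_that("frame counters unwrap across the modulus", {
  expect_identical(unwrap_frame_counter(c(5, 6, 7)), c(5, 6, 7))
  m <- 2^32
  expect_identical(unwrap_frame_counter(c(m - 2, m - 1, 0, 1)),
                   c(m - 2, m - 1, m, m + 1))
  expect_identical(unwrap_frame_counter(c(250, 255, 3), modulus = 256),
                   c(250, 255, 259))
  expect_error(unwrap_frame_counter(c(3, 3)),
               class = "respirad_duplicate_frame_error")
  expect_error(unwrap_frame_counter(c(-1, 2)),
               class = "respirad_counter_error")
})

test_that("effective-range selection keeps exactly the in-window bins", {
  fm <- quiet_frames(duration = 1)
  eff <- select_effective_bins(fm)
  expect_equal(ncol(eff$amplitudes), 27)
  expect_equal(nrow(eff$amplitudes), nrow(fm$amplitudes))
  pos <- bin_positions(eff$config)
  expect_true(all(pos >= 0.2 & pos <= 1.6))

  wide_cfg <- radar_config(effective_range = c(0.18, 0.18 + 180 * 0.0514))
  wide <- frame_matrix(fm$amplitudes, fm$frame_counters, wide_cfg)
  expect_equal(ncol(select_effective_bins(wide)$amplitudes), 181)

  # an interval narrower than one bin that straddles no grid point
  gap_cfg <- radar_config(effective_range = c(0.19, 0.20))
  gap <- frame_matrix(fm$amplitudes, fm$frame_counters, gap_cfg)
  expect_error(select_effective_bins(gap),
               class = "respirad_empty_selection_error")
})

test_that("trapezoidal area matches closed forms and the pracma oracle", {
  expect_equal(area_under_curve(rep(1, 27), 0.0514), 26 * 0.0514)
  expect_equal(area_under_curve(rep(0, 10), 1), 0)
  expect_equal(area_under_curve(c(0, 1, 0), 1), 1)
  expect_error(area_under_curve(1, 1),
               class = "respirad_insufficient_support_error")
  expect_error(area_under_curve(c(1, 2), 0), class = "respirad_config_error")

  skip_if_not_installed("pracma")
  set.seed(42)
  for (i in 1:5) {
    x <- seq(0, 1, length.out = sample(5:60, 1))
    y <- exp(-x) * sin(3 * x) + rnorm(length(x), sd = 0.1)
    expect_equal(area_under_curve(y, diff(x[1:2])),
                 pracma::trapz(x, y), tolerance = 1e-12)
  }
})

test_that("area is linear in the amplitudes", {
  set.seed(7)
  row <- runif(27)
  expect_equal(area_under_curve(3.7 * row, 0.0514),
               3.7 * area_under_curve(row, 0.0514))
  fm <- quiet_frames(duration = 2)
  eff <- select_effective_bins(fm)
  scaled <- frame_matrix(2.5 * eff$amplitudes, eff$frame_counters, eff$config)
  expect_equal(build_auc_series(scaled)$value,
               2.5 * build_auc_series(eff)$value)
})

test_that("the area series has one value per frame, in counter order", {
  fm <- quiet_frames(duration = 10)
  auc <- build_auc_series(select_effective_bins(fm))
  expect_equal(nrow(auc), 200)
  expect_equal(attr(auc, "frame_rate"), 20)

  const <- frame_matrix(matrix(1, 5, 27), 0:4,
                        radar_config(n_bins = 27, range_start = 0.2314))
  expect_equal(build_auc_series(const)$value, rep(26 * 0.0514, 5))

  one <- frame_matrix(matrix(1, 1, 27), 0,
                      radar_config(n_bins = 27, range_start = 0.2314))
  expect_equal(nrow(build_auc_series(one)), 1)
})

test_that("dropped frames are repaired onto the uniform grid", {
  fm <- quiet_frames(duration = 5)
  eff <- select_effective_bins(fm)
  keep <- setdiff(seq_len(100), c(40, 41, 70))
  gappy <- frame_matrix(eff$amplitudes[keep, ], eff$frame_counters[keep],
                        eff$config)
  auc <- build_auc_series(gappy)
  expect_equal(nrow(auc), 100)
  full <- build_auc_series(eff)
  expect_equal(auc$value[-c(40, 41, 70)], full$value[-c(40, 41, 70)])
  # interpolated values sit between their neighbours
  expect_true(auc$value[70] >= min(full$value[69], full$value[71]) &&
                auc$value[70] <= max(full$value[69], full$value[71]))
})

test_that("the spectrum finds tones where they belong", {
  s <- tone_series(0.25, duration = 60)
  sp <- compute_spectrum(s)
  expect_equal(sp$freq_hz[which.max(sp$magnitude)], 0.25)
  expect_equal(max(sp$freq_hz), 10)
  expect_equal(diff(sp$freq_hz[1:2]), 20 / nrow(s))

  flat <- compute_spectrum(make_series(rep(2.5, 100)))
  expect_true(all(abs(flat$magnitude) < 1e-12))

  t <- (0:1199) / 20
  two <- make_series(sin(2 * pi * 0.2 * t) + sin(2 * pi * 2 * t))
  sp2 <- compute_spectrum(two)
  h1 <- sp2$magnitude[which.min(abs(sp2$freq_hz - 0.2))]
  h2 <- sp2$magnitude[which.min(abs(sp2$freq_hz - 2))]
  expect_equal(h1, h2, tolerance = 1e-9)
  expect_equal(h1, 1, tolerance = 1e-9) # unit amplitude, bin-aligned tone

  expect_error(compute_spectrum(make_series(c(1, NA, 3))),
               class = "respirad_series_error")
})

test_that("the filter leaves DC and the passband intact", {
  const <- make_series(rep(3.5, 500))
  expect_equal(lowpass_filter(const)$value, rep(3.5, 500), tolerance = 1e-9)

  s <- tone_series(0.1, duration = 120) # normalized 0.01, well inside passband
  out <- lowpass_filter(s)
  expect_equal(nrow(out), nrow(s))
  expect_equal(fitted_tone_amplitude(out$value, 0.1), 1, tolerance = 0.01)
})

test_that("the heartbeat band is crushed by twenty orders of roll-off", {
  s <- tone_series(1.2, duration = 120)
  out <- lowpass_filter(s)
  expect_lt(fitted_tone_amplitude(out$value, 1.2), 1e-6)
})

test_that("measured attenuation matches the closed-form magnitude oracle", {
  spec <- filter_spec()
  for (wn in c(0.005, 0.01, 0.02, 0.08, 0.2)) {
    f <- wn * 10
    s <- tone_series(f, duration = 600, phase = 0.7)
    meas <- fitted_tone_amplitude(lowpass_filter(s, spec)$value, f)
    pred <- 1 / (1 + (wn / 0.04)^20) # |H|^2: forward and backward pass
    expect_equal(meas, pred, tolerance = 0.05)
  }
})

test_that("passband behaviour agrees with an independent filtfilt realization", {
  skip_if_not_installed("signal")
  s <- tone_series(0.1, duration = 120, offset = 2)
  ours <- lowpass_filter(s)$value
  bf <- signal::butter(10, 0.04)
  theirs <- signal::filtfilt(bf, s$value)
  idx <- 600:1800 # away from both realizations' edge transients
  expect_equal(ours[idx], theirs[idx], tolerance = 0.01)
})

test_that("degenerate filter inputs are rejected", {
  expect_error(filter_spec(cutoff_normalized = 0),
               class = "respirad_filter_error")
  expect_error(filter_spec(cutoff_normalized = 1),
               class = "respirad_filter_error")
  expect_error(filter_spec(order = 0), class = "respirad_filter_error")
  expect_error(lowpass_filter(make_series(rnorm(20))),
               class = "respirad_insufficient_length_error")
  expect_error(lowpass_filter(make_series(c(rep(1, 50), Inf))),
               class = "respirad_series_error")
})
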