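test_that("peak counting converts breaths to RPM", {
  s <- tone_series(0.25, duration = 60)
  res <- count_rpm(s, duration_min = 1)
  expect_equal(res$peak_count, 15)
  expect_equal(res$rpm, 15)
  expect_equal(res$rpm_raw, 15)

  flat <- count_rpm(make_series(rep(1, 100)), duration_min = 1)
  expect_equal(flat$rpm, 0)
  expect_equal(flat$peak_count, 0)

  # 0.4 Hz at 20 frames/s lands peaks exactly between samples (plateaus)
  res24 <- count_rpm(tone_series(0.4, duration = 60), duration_min = 1)
  expect_equal(res24$peak_count, 24)

  expect_equal(count_rpm(s)$duration_min, 1) # inferred from length and rate
  expect_error(count_rpm(s, duration_min = 0), class = "respirad_config_error")
})

test_that("rounding of the raw RPM ratio is half-up", {
  s <- tone_series(0.25, duration = 60)
  res <- count_rpm(s, duration_min = 2) # 15 peaks / 2 min
  expect_equal(res$rpm_raw, 7.5)
  expect_equal(res$rpm, 8)
})

test_that("the full chain recovers a noisy 1-minute recording", {
  fm <- simulate_frames(chest_motion(breathing_rate = 21, seed = 3),
                        default_cfg, 60)
  ex <- extract_rpm(fm)
  expect_equal(ex$result$rpm, 21)
  expect_s3_class(ex$auc, "auc_series")
  expect_s3_class(ex$spectrum, "rpm_spectrum")
  expect_s3_class(ex$respiration, "respiration_signal")
  expect_equal(nrow(ex$respiration), nrow(ex$auc))
})

test_that("a stationary target yields zero RPM", {
  fm <- simulate_frames(
    chest_motion(breathing_amplitude = 0, heart_amplitude = 0,
                 noise_sd = 0, rx_noise_sd = 0, seed = 1),
    default_cfg, 60)
  expect_equal(extract_rpm(fm)$result$rpm, 0)
})

test_that("the default cutoff is 0.4 Hz on the default 10 Hz Nyquist", {
  spec <- filter_spec()
  nyquist <- radar_config()$frame_rate / 2
  expect_equal(spec$cutoff_normalized * nyquist, 0.4)
  expect_equal(spec$cutoff_normalized, 0.04)
  expect_equal(spec$order, 10L)
})

test_that("heartbeat at 10% relative amplitude never changes the count", {
  for (r in c(8, 14, 20)) {
    plain <- quiet_frames(rate = r, duration = 60)
    beat <- simulate_frames(
      chest_motion(breathing_rate = r, noise_sd = 0, rx_noise_sd = 0,
                   heart_amplitude = 5e-4, seed = 1),
      default_cfg, 60)
    expect_equal(extract_rpm(beat)$result$rpm, extract_rpm(plain)$result$rpm)
    expect_equal(extract_rpm(plain)$result$rpm, r)
  }
})

test_that("reference validation is the mean absolute difference", {
  expect_equal(validate_against_reference(
    tibble::tibble(reference_rpm = c(10, 20), extracted_rpm = c(12, 18))), 2)
  same <- tibble::tibble(reference_rpm = 1:5, extracted_rpm = 1:5)
  expect_equal(validate_against_reference(same), 0)
  expect_error(validate_against_reference(same[0, ]),
               class = "respirad_invalid_input_error")
  expect_error(validate_against_reference(data.frame(a = 1)),
               class = "respirad_invalid_input_error")
})

test_that("bundled validation tables have the published shape", {
  bench <- rpm_reference_pairs("bench")
  expect_equal(nrow(bench), 6)
  expect_equal(validate_against_reference(bench), 0)
  driving <- rpm_reference_pairs("driving")
  expect_equal(nrow(driving), 12)
  expect_true(all(abs(driving$reference_rpm - driving$extracted_rpm) <= 1))
})
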