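#' Radar geometry and timing configuration
#'
#' Describes the baseband output grid of an IR-UWB radar: frames arrive at
#' `frame_rate` frames/s and each frame holds one amplitude per range bin on a
#' uniform grid `r_k = range_start + k * bin_length`, `k = 0, ..., n_bins - 1`.
#' Defaults match the X4-class sensor used for in-cabin respiration sensing:
#' 20 frames/s, 181 bins of 0.0514 m starting at 0.18 m, with the driver's
#' chest expected inside the 0.2-1.6 m effective range (27 bins).
#'
#' @param frame_rate Frames per second. Default 20.
#' @param n_bins Number of range bins. Default 181.
#' @param bin_length Bin spacing in metres. Default 0.0514.
#' @param range_start Position of bin 0 in metres. Default 0.18.
#' @param effective_range Length-2 numeric, metres: the distance window whose
#'   bins feed the respiration pipeline. Default `c(0.2, 1.6)`.
#'
#' @return An object of class `radar_config`.
#' @examples
#' cfg <- radar_config()
#' length(effective_bin_index(cfg)) # 27 bins in the default effective range
#' @export
radar_config <- function(frame_rate = 20, n_bins = 181, bin_length = 0.0514,
                         range_start = 0.18, effective_range = c(0.2, 1.6)) {
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  check_number(n_bins, "n_bins", min = 1)
  check_number(bin_length, "bin_length", min = 0, strict_min = TRUE)
  check_number(range_start, "range_start", min = 0)
  if (!is.numeric(effective_range) || length(effective_range) != 2L ||
      any(!is.finite(effective_range)) ||
      effective_range[1] >= effective_range[2]) {
    abort_respirad("`effective_range` must be an increasing numeric interval.",
                   "respirad_config_error")
  }
  span <- c(range_start, range_start + (n_bins - 1) * bin_length)
  if (effective_range[1] < span[1] - bin_length ||
      effective_range[2] > span[2] + bin_length) {
    abort_respirad(
      sprintf("`effective_range` [%g, %g] lies outside the radar span [%g, %g].",
              effective_range[1], effective_range[2], span[1], span[2]),
      "respirad_config_error")
  }
  structure(
    list(frame_rate = frame_rate, n_bins = as.integer(n_bins),
         bin_length = bin_length, range_start = range_start,
         effective_range = as.numeric(effective_range)),
    class = "radar_config")
}

#' Range-bin positions of a radar configuration
#'
#' @param config A [radar_config()].
#' @return Numeric vector of bin positions in metres (length `n_bins`).
#' @export
bin_positions <- function(config) {
  stopifnot(inherits(config, "radar_config"))
  config$range_start + (seq_len(config$n_bins) - 1) * config$bin_length
}

#' Indices of bins inside the effective range
#'
#' A bin belongs to the effective range iff its grid position lies in the
#' closed interval `effective_range`.
#'
#' @inheritParams bin_positions
#' @return Integer vector of column indices (1-based).
#' @export
effective_bin_index <- function(config) {
  r <- bin_positions(config)
  which(r >= config$effective_range[1] & r <= config$effective_range[2])
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  frame_rate: %g frames/s\n", x$frame_rate))
  cat(sprintf("  bins: %d x %g m from %g m\n", x$n_bins, x$bin_length,
              x$range_start))
  cat(sprintf("  effective range: [%g, %g] m (%d bins)\n",
              x$effective_range[1], x$effective_range[2],
              length(effective_bin_index(x))))
  invisible(x)
}

#' Chest-motion model for the radar simulator
#'
#' Parametric model of the chest-radar distance
#' `d(t) = target_distance - x(t)` with
#' `x(t) = A_b sin(2 pi f_b t) + A_h sin(2 pi f_h t) + eps(t)`:
#' a breathing sinusoid, a smaller heartbeat sinusoid, and zero-mean Gaussian
#' displacement noise with sd `noise_sd * breathing_amplitude`. Inhaling
#' shortens the chest-radar distance, which raises the received amplitude.
#'
#' @param target_distance Nominal chest-radar distance `d0` in metres.
#' @param breathing_rate True breathing rate in breaths/min. Adult respiration
#'   tops out near 24 breaths/min (0.4 Hz); any positive rate is accepted so
#'   out-of-band rejection can be exercised.
#' @param breathing_amplitude Chest excursion in metres. Default 0.005.
#' @param heart_rate Heart rate in beats/min. Default 72.
#' @param heart_amplitude Heartbeat excursion in metres. Default 5e-4.
#' @param noise_sd Displacement noise, relative to `breathing_amplitude`.
#' @param rx_noise_sd Receiver amplitude noise, relative to the nominal peak
#'   amplitude; clipped at zero after addition. Default 0.001 (the sensor's
#'   internal pulse integration leaves baseband magnitude noise well below the
#'   breathing modulation; see the methods vignette).
#' @param pulse_width Spatial spread (Gaussian sigma, metres) of the reflected
#'   pulse across range bins. Default 0.05.
#' @param gain Amplitude scale `G` of the `G / d(t)^2` spreading law.
#' @param spreading_exponent Exponent of the spreading law. Default 2.
#' @param clutter Optional static background amplitude profile added to every
#'   frame (length `n_bins`), or `NULL`.
#' @param seed Integer seed for the simulation noise streams.
#'
#' @return An object of class `chest_motion`.
#' @export
chest_motion <- function(target_distance = 1.0, breathing_rate = 15,
                         breathing_amplitude = 0.005, heart_rate = 72,
                         heart_amplitude = 5e-4, noise_sd = 0.1,
                         rx_noise_sd = 0.001, pulse_width = 0.05, gain = 1,
                         spreading_exponent = 2, clutter = NULL, seed = 1L) {
  check_number(target_distance, "target_distance", min = 0, strict_min = TRUE)
  check_number(breathing_rate, "breathing_rate", min = 0)
  check_number(breathing_amplitude, "breathing_amplitude", min = 0)
  check_number(heart_rate, "heart_rate", min = 0)
  check_number(heart_amplitude, "heart_amplitude", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(rx_noise_sd, "rx_noise_sd", min = 0)
  check_number(pulse_width, "pulse_width", min = 0, strict_min = TRUE)
  check_number(gain, "gain", min = 0, strict_min = TRUE)
  if (heart_amplitude > breathing_amplitude) {
    abort_respirad("`heart_amplitude` must not exceed `breathing_amplitude`.",
                   "respirad_config_error")
  }
  structure(
    list(target_distance = target_distance, breathing_rate = breathing_rate,
         breathing_amplitude = breathing_amplitude, heart_rate = heart_rate,
         heart_amplitude = heart_amplitude, noise_sd = noise_sd,
         rx_noise_sd = rx_noise_sd, pulse_width = pulse_width, gain = gain,
         spreading_exponent = spreading_exponent, clutter = clutter,
         seed = as.integer(seed)),
    class = "chest_motion")
}

#' @export
print.chest_motion <- function(x, ...) {
  cat("<chest_motion>\n")
  cat(sprintf("  target %g m; breathing %g bpm (A=%g m); heart %g bpm (A=%g m)\n",
              x$target_distance, x$breathing_rate, x$breathing_amplitude,
              x$heart_rate, x$heart_amplitude))
  cat(sprintf("  noise_sd %g (rel), rx_noise_sd %g, seed %d\n",
              x$noise_sd, x$rx_noise_sd, x$seed))
  invisible(x)
}

#' Low-pass filter specification
#'
#' A Butterworth low-pass described by its order and cutoff as a fraction of
#' the Nyquist frequency. The defaults are order 10 with normalized cutoff
#' 0.04: at 20 frames/s the Nyquist frequency is 10 Hz, so 0.04 corresponds to
#' 0.4 Hz, the adult maximum respiration frequency.
#'
#' @param order Filter order, >= 1. Default 10.
#' @param cutoff_normalized Cutoff as a fraction of Nyquist, in (0, 1).
#'   Default 0.04.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 10, cutoff_normalized = 0.04) {
  if (!is_number(order) || order < 1) {
    abort_respirad("`order` must be a number >= 1.", "respirad_filter_error")
  }
  if (!is_number(cutoff_normalized) ||
      cutoff_normalized <= 0 || cutoff_normalized >= 1) {
    abort_respirad("`cutoff_normalized` must lie strictly inside (0, 1).",
                   "respirad_filter_error")
  }
  structure(list(order = as.integer(order),
                 cutoff_normalized = cutoff_normalized,
                 kind = "low-pass"),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> Butterworth low-pass, order %d, cutoff %g x Nyquist\n",
              x$order, x$cutoff_normalized))
  invisible(x)
}
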