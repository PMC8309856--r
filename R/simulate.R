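#' Construct a radar frame matrix
#'
#' Container for baseband radar data: an `n_frames x n_bins` nonnegative
#' amplitude matrix, a per-frame counter (modulo 2^32 on the sensor), and the
#' [radar_config()] that produced it.
#'
#' @param amplitudes Numeric matrix, rows = frames (time), columns = range bins.
#' @param frame_counters Numeric vector of per-frame counters (one per row).
#' @param config A [radar_config()]; `config$n_bins` must equal `ncol(amplitudes)`.
#' @param seed Optional integer recorded as simulation metadata.
#'
#' @return An object of class `frame_matrix`.
#' @export
frame_matrix <- function(amplitudes, frame_counters, config, seed = NULL) {
  amplitudes <- as.matrix(amplitudes)
  if (ncol(amplitudes) != config$n_bins) {
    abort_respirad(
      sprintf("amplitude matrix has %d columns but config$n_bins is %d.",
              ncol(amplitudes), config$n_bins),
      "respirad_format_error")
  }
  if (length(frame_counters) != nrow(amplitudes)) {
    abort_respirad("`frame_counters` must have one entry per frame row.",
                   "respirad_format_error")
  }
  structure(
    list(amplitudes = unname(amplitudes),
         frame_counters = as.numeric(frame_counters),
         config = config, seed = seed),
    class = "frame_matrix")
}

#' Simulate IR-UWB baseband frames from a chest-motion model
#'
#' Generates the frame matrix a radar would record in front of a breathing
#' subject. At each frame time `t` the chest sits at
#' `d(t) = d0 - x(t)` (inhaling shortens the distance); the received amplitude
#' profile across bins is a Gaussian pulse envelope of spatial width
#' `pulse_width` centred at `d(t)`, scaled by the spreading gain
#' `G / d(t)^p` (default `p = 2`), plus optional static clutter and per-sample
#' receiver noise clipped at zero. Deterministic given `motion$seed`.
#'
#' @param motion A [chest_motion()] model.
#' @param config A [radar_config()].
#' @param duration Recording length in seconds (> 0).
#'
#' @return A [frame_matrix()] with `duration * frame_rate` rows.
#' @examples
#' fm <- simulate_frames(chest_motion(breathing_rate = 15, seed = 42),
#'                       radar_config(), duration = 30)
#' dim(fm$amplitudes)
#' @export
simulate_frames <- function(motion, config = radar_config(), duration = 300) {
  stopifnot(inherits(motion, "chest_motion"), inherits(config, "radar_config"))
  if (!is_number(duration) || duration <= 0) {
    abort_respirad("`duration` must be a positive number of seconds.",
                   "respirad_config_error")
  }
  span <- range(bin_positions(config))
  if (motion$target_distance < span[1] || motion$target_distance > span[2]) {
    abort_respirad(
      sprintf("target_distance %g m is outside the radar bin span [%g, %g] m.",
              motion$target_distance, span[1], span[2]),
      "respirad_config_error")
  }
  n <- round(duration * config$frame_rate)
  t <- (seq_len(n) - 1) / config$frame_rate
  r <- bin_positions(config)

  withr::with_seed(motion$seed, {
    eps <- if (motion$noise_sd > 0) {
      stats::rnorm(n, sd = motion$noise_sd * motion$breathing_amplitude)
    } else {
      numeric(n)
    }
    x <- motion$breathing_amplitude * sin(2 * pi * motion$breathing_rate / 60 * t) +
      motion$heart_amplitude * sin(2 * pi * motion$heart_rate / 60 * t) + eps
    d <- motion$target_distance - x
    # pulse envelope across bins, scaled by the two-way spreading gain
    amp <- (motion$gain / d^motion$spreading_exponent) *
      exp(-outer(d, r, `-`)^2 / (2 * motion$pulse_width^2))
    if (!is.null(motion$clutter)) {
      amp <- sweep(amp, 2, rep_len(motion$clutter, config$n_bins), `+`)
    }
    if (motion$rx_noise_sd > 0) {
      peak <- motion$gain / motion$target_distance^motion$spreading_exponent
      amp <- amp + matrix(stats::rnorm(n * config$n_bins,
                                       sd = motion$rx_noise_sd * peak),
                          nrow = n)
    }
  })
  amp[amp < 0] <- 0
  frame_matrix(amp, frame_counters = seq_len(n) - 1, config = config,
               seed = motion$seed)
}

#' @export
print.frame_matrix <- function(x, ...) {
  cat(sprintf("<frame_matrix> %d frames x %d bins at %g frames/s (%.1f s)\n",
              nrow(x$amplitudes), ncol(x$amplitudes), x$config$frame_rate,
              nrow(x$amplitudes) / x$config$frame_rate))
  invisible(x)
}

#' @export
dim.frame_matrix <- function(x) dim(x$amplitudes)

#' Tidy a frame matrix into a long tibble
#'
#' @param x A [frame_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `range_m`, `amplitude`.
#' @importFrom generics tidy
#' @export
tidy.frame_matrix <- function(x, ...) {
  r <- bin_positions(x$config)
  n <- nrow(x$amplitudes)
  tibble::tibble(
    time_s = rep((seq_len(n) - 1) / x$config$frame_rate, times = length(r)),
    range_m = rep(r, each = n),
    amplitude = as.vector(x$amplitudes))
}
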