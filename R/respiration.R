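#' Unwrap a modulo frame counter
#'
#' Radar frame counters increase by one per frame and wrap to 0 at the modulus
#' (2^32 on the sensor). Unwrapping restores a strictly increasing sequence
#' with the minimal number of wrap additions, so dropped frames can be
#' detected as gaps.
#'
#' @param counters Numeric vector of raw counters, each in `[0, modulus)`.
#' @param modulus Counter modulus. Default `2^32`.
#'
#' @return Numeric vector, strictly increasing, congruent to `counters`
#'   modulo `modulus`.
#' @examples
#' unwrap_frame_counter(c(2^32 - 2, 2^32 - 1, 0, 1))
#' @export
unwrap_frame_counter <- function(counters, modulus = 2^32) {
  counters <- as.numeric(counters)
  if (length(counters) == 0) return(counters)
  if (any(counters < 0 | counters >= modulus)) {
    abort_respirad("counters must lie in [0, modulus).", "respirad_counter_error")
  }
  if (length(counters) > 1 && any(diff(counters) == 0)) {
    abort_respirad("duplicate frame counter value within one wrap period.",
                   "respirad_duplicate_frame_error")
  }
  wraps <- cumsum(c(0, diff(counters) < 0))
  counters + wraps * modulus
}

#' Restrict a frame matrix to the effective-range bins
#'
#' Keeps exactly the columns whose bin position
#' `r_k = range_start + k * bin_length` lies inside the closed interval
#' `config$effective_range`. With the default geometry this retains 27 of the
#' 181 bins (0.2-1.6 m, where the driver's chest is expected).
#'
#' @param frames A [frame_matrix()].
#' @return A [frame_matrix()] whose config spans only the retained columns.
#' @export
select_effective_bins <- function(frames) {
  stopifnot(inherits(frames, "frame_matrix"))
  cfg <- frames$config
  keep <- effective_bin_index(cfg)
  if (length(keep) == 0) {
    abort_respirad(
      sprintf("no bin position falls inside effective_range [%g, %g].",
              cfg$effective_range[1], cfg$effective_range[2]),
      "respirad_empty_selection_error")
  }
  sub_cfg <- radar_config(
    frame_rate = cfg$frame_rate, n_bins = length(keep),
    bin_length = cfg$bin_length,
    range_start = cfg$range_start + (keep[1] - 1) * cfg$bin_length,
    effective_range = cfg$effective_range)
  frame_matrix(frames$amplitudes[, keep, drop = FALSE],
               frame_counters = frames$frame_counters,
               config = sub_cfg, seed = frames$seed)
}

#' Area under one frame's amplitude curve
#'
#' Composite trapezoidal rule over a uniformly spaced amplitude profile:
#' `spacing * sum((v_i + v_{i+1}) / 2)`.
#'
#' @param frame_row Numeric vector of amplitudes over bins (length >= 2).
#' @param spacing Bin spacing in metres (> 0).
#' @return Area scalar (amplitude x metres).
#' @examples
#' area_under_curve(c(0, 1, 0), spacing = 1) # triangle: 1
#' @export
area_under_curve <- function(frame_row, spacing) {
  if (length(frame_row) < 2) {
    abort_respirad("trapezoidal area needs at least 2 values.",
                   "respirad_insufficient_support_error")
  }
  check_number(spacing, "spacing", min = 0, strict_min = TRUE)
  n <- length(frame_row)
  spacing * sum((frame_row[-n] + frame_row[-1]) / 2)
}

#' Build the per-frame area series (vector A)
#'
#' Applies [area_under_curve()] to every frame of an effective-bin-restricted
#' matrix, in frame-counter order, producing the motion-carrying time series
#' at the frame rate (a 5-minute recording at 20 frames/s gives 6000 values).
#' Gaps flagged by the unwrapped frame counter (dropped frames) are filled by
#' linear interpolation onto the uniform frame grid, since the downstream
#' filter assumes uniform sampling.
#'
#' @param frames A [frame_matrix()], already restricted to effective bins.
#' @return An `auc_series` tibble with columns `time_s`, `value`, plus a
#'   `frame_rate` attribute.
#' @export
build_auc_series <- function(frames) {
  stopifnot(inherits(frames, "frame_matrix"))
  areas <- apply(frames$amplitudes, 1, area_under_curve,
                 spacing = frames$config$bin_length)
  counters <- unwrap_frame_counter(frames$frame_counters)
  if (is.unsorted(counters, strictly = TRUE)) {
    ord <- order(counters)
    counters <- counters[ord]
    areas <- areas[ord]
  }
  rel <- counters - counters[1]
  if (length(areas) > 1 && any(diff(rel) != 1)) {
    grid <- seq(0, rel[length(rel)])
    areas <- stats::approx(rel, areas, xout = grid)$y
    rel <- grid
  }
  new_auc_series(areas, frame_rate = frames$config$frame_rate)
}

new_auc_series <- function(values, frame_rate, class = "auc_series") {
  out <- tibble::tibble(
    time_s = (seq_along(values) - 1) / frame_rate,
    value = as.numeric(values))
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c(class, class(tibble::tibble()))
  out
}

series_rate <- function(series, arg = "series") {
  fr <- attr(series, "frame_rate")
  if (is.null(fr)) {
    abort_respirad(sprintf("`%s` has no frame_rate attribute; build it with build_auc_series() or lowpass_filter().", arg),
                   "respirad_series_error")
  }
  fr
}

#' One-sided magnitude spectrum of an area series
#'
#' Removes the series mean (the large static offset from the stationary body
#' and clutter would otherwise mask the breathing peak) and returns the
#' one-sided discrete Fourier magnitude on `[0, frame_rate / 2]`.
#'
#' @param series An `auc_series` (or `respiration_signal`) tibble.
#' @return A `rpm_spectrum` tibble with columns `freq_hz`, `magnitude`.
#' @export
compute_spectrum <- function(series) {
  v <- series$value
  if (length(v) < 2) {
    abort_respirad("spectrum needs a series of length >= 2.",
                   "respirad_series_error")
  }
  if (any(!is.finite(v))) {
    abort_respirad("series contains non-finite values.", "respirad_series_error")
  }
  fr <- series_rate(series)
  n <- length(v)
  mag <- Mod(stats::fft(v - mean(v))) / n
  keep <- seq_len(n %/% 2 + 1)
  mag <- mag[keep]
  # fold two-sided power into the one-sided magnitudes (not DC / Nyquist)
  interior <- setdiff(seq_along(mag), c(1, if (n %% 2 == 0) length(mag)))
  mag[interior] <- 2 * mag[interior]
  out <- tibble::tibble(freq_hz = (keep - 1) * fr / n, magnitude = mag)
  class(out) <- c("rpm_spectrum", class(tibble::tibble()))
  out
}

# squared Butterworth low-pass magnitude (forward-backward application)
butterworth_gain2 <- function(f_norm, order, cutoff) {
  1 / (1 + (abs(f_norm) / cutoff)^(2 * order))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies the Butterworth low-pass of `spec` forward and backward (zero
#' phase), realized in the frequency domain: the series is extended by odd
#' reflection at both ends (removing boundary discontinuities, as forward-
#' backward IIR padding does) and its spectrum multiplied by the squared
#' Butterworth magnitude `|H(f)|^2 = 1 / (1 + (f / f_c)^(2 order))`. Zero
#' phase keeps breath peaks in place so they can be counted; DC gain is
#' exactly 1.
#'
#' @param series An `auc_series` tibble (length > 3 x order).
#' @param spec A [filter_spec()]. Default order 10, cutoff 0.04 x Nyquist
#'   (0.4 Hz at 20 frames/s).
#' @return A `respiration_signal` tibble (`time_s`, `value`), same length as
#'   the input.
#' @export
lowpass_filter <- function(series, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  v <- series$value
  if (any(!is.finite(v))) {
    abort_respirad("series contains non-finite values.", "respirad_series_error")
  }
  n <- length(v)
  if (n <= 3 * spec$order) {
    abort_respirad(
      sprintf("series of length %d is too short for a stable order-%d filter (needs > %d).",
              n, spec$order, 3 * spec$order),
      "respirad_insufficient_length_error")
  }
  fr <- series_rate(series)
  p <- n - 1
  # reflection anchors from a short linear fit at each end: reflecting about a
  # single raw sample would imprint that sample's broadband noise as a
  # low-frequency boundary transient comparable to the breathing modulation
  anchor <- function(idx, at) {
    co <- stats::lm.fit(cbind(1, idx), v[idx])$coefficients
    co[1] + co[2] * at
  }
  L <- min(5L, n)
  a1 <- anchor(seq_len(L), 1)
  an <- anchor(seq.int(n - L + 1, n), n)
  ext <- c(2 * a1 - v[(p + 1):2], v, 2 * an - v[(n - 1):(n - p)])
  m <- length(ext)
  f_norm <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / m * 2
  g <- butterworth_gain2(f_norm, spec$order, spec$cutoff_normalized)
  filt <- Re(stats::fft(stats::fft(ext) * g, inverse = TRUE) / m)[(p + 1):(p + n)]
  new_auc_series(filt, frame_rate = fr, class = "respiration_signal")
}

# plateau-aware local maxima with prominence and minimum separation;
# plateaus are assigned to their earliest sample
find_signal_peaks <- function(x, min_separation, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the previous non-zero slope through plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  rising <- which(diff(s) < 0 & s[-length(s)] > 0)
  cand <- rising + 1L
  # move each candidate to the earliest sample of its plateau
  cand <- vapply(cand, function(i) {
    while (i > 1L && x[i - 1L] == x[i]) i <- i - 1L
    i
  }, integer(1))
  cand <- unique(cand)
  if (length(cand) == 0) return(integer(0))
  side_min <- function(vals, h) {
    # minimum between the peak and the nearest higher sample (or signal edge)
    if (length(vals) == 0) return(-Inf)
    hi <- which(vals > h)
    window <- if (length(hi)) vals[seq_len(hi[1] - 1)] else vals
    if (length(window) == 0) -Inf else min(window)
  }
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- side_min(rev(x[seq_len(i - 1)]), h)
    rmin <- side_min(if (i < n) x[seq.int(i + 1, n)] else numeric(0), h)
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1) return(keep)
  # enforce separation, keeping higher peaks first (ties -> earliest sample)
  ord <- order(-x[keep], keep)
  sel <- logical(length(keep))
  taken <- integer(0)
  for (j in ord) {
    if (all(abs(keep[j] - taken) >= min_separation)) {
      sel[j] <- TRUE
      taken <- c(taken, keep[j])
    }
  }
  sort(keep[sel])
}

#' Count breaths and convert to respiration per minute
#'
#' Counts peaks of the filtered respiration signal and divides by the
#' recording duration in minutes. A peak is a local maximum (earliest sample
#' of a plateau) with prominence at least
#' `prominence_factor x sd(signal)` and at least
#' `frame_rate x 60 / (2 x max_breaths_per_min)` samples from any higher
#' accepted peak — half the period of the fastest physiological breathing
#' rate (0.4 Hz, 24 breaths/min, by default).
#'
#' @param signal A `respiration_signal` (or `auc_series`) tibble.
#' @param duration_min Recording duration in minutes (> 0). Defaults to the
#'   signal length over the frame rate.
#' @param max_breaths_per_min Fastest breathing rate considered. Default 24.
#' @param prominence_factor Prominence floor as a multiple of the signal
#'   standard deviation. Default 0.5.
#' @return An `rpm_result` list: `peak_count`, `duration_min`, `rpm_raw`
#'   (exact ratio), `rpm` (rounded half-up to integer), `peak_index`.
#' @examples
#' fm <- simulate_frames(chest_motion(breathing_rate = 12, noise_sd = 0, seed = 1),
#'                       radar_config(), duration = 60)
#' sig <- lowpass_filter(build_auc_series(select_effective_bins(fm)))
#' count_rpm(sig)$rpm # 12
#' @export
count_rpm <- function(signal, duration_min = NULL, max_breaths_per_min = 24,
                      prominence_factor = 0.5) {
  v <- signal$value
  if (length(v) == 0) {
    abort_respirad("signal is empty.", "respirad_series_error")
  }
  fr <- series_rate(signal, "signal")
  if (is.null(duration_min)) duration_min <- length(v) / fr / 60
  check_number(duration_min, "duration_min", min = 0, strict_min = TRUE)
  scale <- max(abs(v))
  v <- v - mean(v)
  sdv <- stats::sd(v)
  # a flat signal carries no breaths; round-off ripple must not count as peaks
  if (!is.finite(sdv) || sdv <= 1e-10 * max(scale, .Machine$double.xmin)) {
    peaks <- integer(0)
  } else {
    min_sep <- fr * 60 / (2 * max_breaths_per_min)
    peaks <- find_signal_peaks(v, min_separation = min_sep,
                               min_prominence = prominence_factor * sdv)
  }
  k <- length(peaks)
  structure(
    list(peak_count = k, duration_min = duration_min,
         rpm_raw = k / duration_min, rpm = round_half_up(k / duration_min),
         peak_index = peaks),
    class = "rpm_result")
}

#' @export
print.rpm_result <- function(x, ...) {
  cat(sprintf("<rpm_result> %d peaks / %g min = %.3f (reported RPM: %d)\n",
              x$peak_count, x$duration_min, x$rpm_raw, x$rpm))
  invisible(x)
}

#' Tidy an RPM result
#'
#' @param x An `rpm_result`.
#' @param ... Unused.
#' @return A one-row tibble: `peak_count`, `duration_min`, `rpm_raw`, `rpm`.
#' @export
tidy.rpm_result <- function(x, ...) {
  tibble::tibble(peak_count = x$peak_count, duration_min = x$duration_min,
                 rpm_raw = x$rpm_raw, rpm = x$rpm)
}

#' Extract respiration rate from a radar frame matrix
#'
#' Runs the full chain: effective-bin selection, per-frame trapezoidal area
#' (vector A), zero-phase Butterworth low-pass, peak counting. The
#' intermediate series and spectrum are returned for inspection.
#'
#' @param frames A full-width [frame_matrix()].
#' @param spec A [filter_spec()]. Default order 10, cutoff 0.04 x Nyquist.
#' @param ... Passed to [count_rpm()] (peak-detection parameters).
#' @return An `rpm_extraction` list: `result` (the [count_rpm()] output),
#'   `auc` (vector A), `spectrum`, `respiration` (filtered signal).
#' @examples
#' fm <- simulate_frames(chest_motion(breathing_rate = 15, noise_sd = 0, seed = 7),
#'                       radar_config(), duration = 60)
#' extract_rpm(fm)$result$rpm
#' @export
extract_rpm <- function(frames, spec = filter_spec(), ...) {
  eff <- select_effective_bins(frames)
  auc <- build_auc_series(eff)
  spectrum <- compute_spectrum(auc)
  respiration <- lowpass_filter(auc, spec)
  result <- count_rpm(respiration, ...)
  structure(list(result = result, auc = auc, spectrum = spectrum,
                 respiration = respiration),
            class = "rpm_extraction")
}

#' @export
print.rpm_extraction <- function(x, ...) {
  print(x$result)
  invisible(x)
}

#' Mean absolute RPM difference against a reference device
#'
#' Summarizes agreement between a reference respiration-rate measurement
#' (e.g. a pulse oximeter) and radar-extracted RPM as the mean absolute
#' difference over paired recordings.
#'
#' @param pairs A data frame with columns `reference_rpm` and `extracted_rpm`
#'   (one row per paired recording).
#' @return Mean of `|reference_rpm - extracted_rpm|`.
#' @examples
#' validate_against_reference(rpm_reference_pairs("driving")) # 0.58 at 2 dp
#' @export
validate_against_reference <- function(pairs) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0) {
    abort_respirad("`pairs` must be a nonempty data frame.",
                   "respirad_invalid_input_error")
  }
  if (!all(c("reference_rpm", "extracted_rpm") %in% names(pairs))) {
    abort_respirad("`pairs` needs columns reference_rpm and extracted_rpm.",
                   "respirad_invalid_input_error")
  }
  mean(abs(pairs$reference_rpm - pairs$extracted_rpm))
}
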