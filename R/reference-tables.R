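#' Reference oximeter/radar RPM validation pairs
#'
#' Paired respiration-per-minute readings from a finger pulse oximeter
#' (reference) and the radar extraction chain, from the two published
#' validation experiments of the method this package implements:
#'
#' * `"bench"` — three seated subjects, two 1-minute sessions each, radar on a
#'   bench in front of the subject (6 pairs; radar and oximeter agree on all).
#' * `"driving"` — six subjects driving at various speeds with the radar on
#'   the dashboard (12 pairs; mean absolute difference 0.58 breaths/min).
#'
#' @param setting `"bench"` or `"driving"`.
#' @return A tibble with columns `subject`, `session`, `reference_rpm`,
#'   `extracted_rpm`, plus `speed_kmh` for the driving setting.
#' @examples
#' validate_against_reference(rpm_reference_pairs("driving"))
#' @export
rpm_reference_pairs <- function(setting = c("bench", "driving")) {
  setting <- match.arg(setting)
  if (setting == "bench") {
    tibble::tibble(
      subject = rep(1:3, each = 2),
      session = rep(1:2, times = 3),
      reference_rpm = c(15, 18, 16, 17, 21, 12),
      extracted_rpm = c(15, 18, 16, 17, 21, 12))
  } else {
    tibble::tibble(
      subject = rep(1:6, each = 2),
      session = rep(1:2, times = 6),
      reference_rpm = c(15, 17, 19, 17, 16, 15, 17, 16, 19, 19, 17, 19),
      extracted_rpm = c(16, 17, 18, 18, 17, 15, 18, 16, 18, 20, 17, 19),
      speed_kmh = c(20, 40, 20, 40, 60, 45, 20, 30, 60, 50, 50, 20))
  }
}
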