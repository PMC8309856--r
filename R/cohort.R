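#' Specification of a synthetic driver cohort
#'
#' The real driver dataset behind this method is withheld, so analyses run on
#' a synthetic cohort that emulates its published structure: paired drowsy /
#' non-drowsy recordings of `n_drivers` professional drivers aged 30-50, a
#' mild age trend in baseline (non-drowsy) respiration rate, and a drowsiness
#' drop in RPM that is larger in younger drivers.
#'
#' Defaults (chosen once as physiologically plausible values consistent with
#' the published description; see the methods vignette): non-drowsy RPM =
#' `26 - 0.12 * age` + noise, so roughly 22.4 breaths/min at 30 y down to
#' 20.0 at 50 y; drowsy RPM sits below it by a drop interpolated linearly
#' from 6 breaths/min at the youngest age to 3 at the oldest; Gaussian noise
#' with sd 1.5 breaths/min on each recording.
#'
#' @param n_drivers Number of drivers; each contributes one drowsy and one
#'   non-drowsy record. Default 40 (80 records).
#' @param age_range Length-2 numeric, years. Default `c(30, 50)`.
#' @param nondrowsy_rpm_intercept,nondrowsy_rpm_slope Baseline RPM linear
#'   model in age: `intercept + slope * age`. Defaults 26 and -0.12.
#' @param drowsy_drop_young,drowsy_drop_old RPM decrease when drowsy at the
#'   youngest / oldest age; must satisfy `young > old >= 0`. Defaults 6, 3.
#' @param noise_sd Per-recording Gaussian noise, breaths/min. Default 1.5.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_drivers = 40, age_range = c(30, 50),
                        nondrowsy_rpm_intercept = 26,
                        nondrowsy_rpm_slope = -0.12,
                        drowsy_drop_young = 6, drowsy_drop_old = 3,
                        noise_sd = 1.5, seed = 1L) {
  check_number(n_drivers, "n_drivers", min = 1)
  if (!is.numeric(age_range) || length(age_range) != 2L ||
      age_range[1] >= age_range[2] || age_range[1] < 18 || age_range[2] > 80) {
    abort_respirad("`age_range` must be an increasing interval within 18-80 years.",
                   "respirad_config_error")
  }
  check_number(nondrowsy_rpm_intercept, "nondrowsy_rpm_intercept")
  check_number(nondrowsy_rpm_slope, "nondrowsy_rpm_slope")
  check_number(drowsy_drop_young, "drowsy_drop_young", min = 0)
  check_number(drowsy_drop_old, "drowsy_drop_old", min = 0)
  if (drowsy_drop_young <= drowsy_drop_old) {
    abort_respirad("`drowsy_drop_young` must exceed `drowsy_drop_old` (the RPM decrease is larger in younger drivers).",
                   "respirad_config_error")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  structure(
    list(n_drivers = as.integer(n_drivers), age_range = as.numeric(age_range),
         nondrowsy_rpm_intercept = nondrowsy_rpm_intercept,
         nondrowsy_rpm_slope = nondrowsy_rpm_slope,
         drowsy_drop_young = drowsy_drop_young,
         drowsy_drop_old = drowsy_drop_old,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a synthetic paired driver cohort
#'
#' Draws driver ages uniformly over `age_range` and, for each driver, one
#' non-drowsy record (`intercept + slope * age` + noise) and one drowsy
#' record (the driver's non-drowsy mean minus an age-interpolated drop, plus
#' its own noise). Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per record and columns `driver_id`, `age`,
#'   `rpm`, `label` (factor, levels `non-drowsy`, `drowsy`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' dplyr::count(cohort, label) # 40 of each
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    age <- stats::runif(spec$n_drivers, spec$age_range[1], spec$age_range[2])
    frac <- (age - spec$age_range[1]) / diff(spec$age_range)
    drop <- spec$drowsy_drop_young +
      frac * (spec$drowsy_drop_old - spec$drowsy_drop_young)
    base <- spec$nondrowsy_rpm_intercept + spec$nondrowsy_rpm_slope * age
    noise <- function() if (spec$noise_sd > 0) {
      stats::rnorm(spec$n_drivers, sd = spec$noise_sd)
    } else {
      numeric(spec$n_drivers)
    }
    nondrowsy <- base + noise()
    drowsy <- base - drop + noise()
  })
  out <- tibble::tibble(
    driver_id = rep(seq_len(spec$n_drivers), 2),
    age = rep(age, 2),
    rpm = c(nondrowsy, drowsy),
    label = factor(rep(c("non-drowsy", "drowsy"), each = spec$n_drivers),
                   levels = c("non-drowsy", "drowsy")))
  out$rpm <- pmax(out$rpm, 1) # RPM is a positive rate
  dplyr::arrange(out, .data$driver_id, .data$label)
}
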