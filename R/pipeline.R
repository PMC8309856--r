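#' Default pipeline configuration
#'
#' All method constants live here, never hard-coded in logic: radar geometry
#' (20 frames/s, 181 bins of 0.0514 m from 0.18 m, effective range
#' 0.2-1.6 m), the order-10 Butterworth at normalized cutoff 0.04, the peak
#' detection parameters, the simulator and cohort generator settings, and the
#' classification protocol (70/30 split, 15 folds, threshold 18.5).
#'
#' @return A nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    radar = list(frame_rate = 20, n_bins = 181, bin_length = 0.0514,
                 range_start = 0.18, effective_range = c(0.2, 1.6)),
    filter = list(order = 10, cutoff_normalized = 0.04),
    peaks = list(max_breaths_per_min = 24, prominence_factor = 0.5),
    motion = list(target_distance = 1.0, breathing_rate = 15,
                  breathing_amplitude = 0.005, heart_rate = 72,
                  heart_amplitude = 5e-4, noise_sd = 0.1,
                  rx_noise_sd = 0.001, pulse_width = 0.05),
    simulate = list(duration = 300),
    cohort = list(n_drivers = 40, age_range = c(30, 50),
                  nondrowsy_rpm_intercept = 26, nondrowsy_rpm_slope = -0.12,
                  drowsy_drop_young = 6, drowsy_drop_old = 3, noise_sd = 1.5),
    protocol = list(train_fraction = 0.70, n_folds = 15, threshold = 18.5,
                    tune = TRUE),
    seed = 1L), class = "run_config")
}

merge_config <- function(defaults, override, path = character()) {
  for (key in names(override)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      abort_respirad(sprintf("unknown configuration key `%s`.", here),
                     "respirad_config_error")
    }
    if (is.list(defaults[[key]])) {
      if (!is.list(override[[key]])) {
        abort_respirad(sprintf("`%s` must be a mapping.", here),
                       "respirad_config_error")
      }
      defaults[[key]] <- merge_config(defaults[[key]], override[[key]], c(path, key))
    } else {
      defaults[[key]] <- if (is.list(override[[key]])) {
        unlist(override[[key]])
      } else {
        override[[key]]
      }
    }
  }
  defaults
}

#' Load a pipeline configuration from YAML
#'
#' Reads a (possibly partial) YAML file and merges it over
#' [default_run_config()]: only the keys present in the file change; unknown
#' keys are rejected with their full key path. An empty file yields the full
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_respirad(sprintf("config file '%s' does not exist.", path),
                   "respirad_config_error")
  }
  override <- yaml::read_yaml(path)
  if (is.null(override)) override <- list()
  cfg <- merge_config(unclass(default_run_config()), override)
  validate_run_config(structure(cfg, class = "run_config"))
}

validate_run_config <- function(config) {
  f <- config$filter
  if (!is_number(f$cutoff_normalized) ||
      f$cutoff_normalized <= 0 || f$cutoff_normalized >= 1) {
    abort_respirad("`filter.cutoff_normalized` must lie strictly inside (0, 1).",
                   "respirad_filter_error")
  }
  if (!is_number(f$order) || f$order < 1) {
    abort_respirad("`filter.order` must be >= 1.", "respirad_filter_error")
  }
  config
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
}

#' Run the end-to-end pipeline
#'
#' Simulates a radar recording (or reads one), extracts RPM with all
#' intermediates, generates the synthetic cohort, runs the classification
#' benchmark, and writes every artifact plus a manifest of seeds and outputs
#' to `out_dir`. Rerunning with an identical configuration reproduces the
#' outputs.
#'
#' @param config A `run_config` (see [default_run_config()],
#'   [load_run_config()]).
#' @param out_dir Output directory; created if missing.
#' @param frames Optional [frame_matrix()] to analyse instead of simulating.
#' @return Invisibly, a list with `extraction`, `cohort`, `benchmark`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("respirad_"),
                         frames = NULL) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_respirad(sprintf("pipeline stage '%s' failed: %s", name,
                             conditionMessage(e)),
                     "respirad_pipeline_error")
    })
  }
  radar <- stage("radar-config", do.call(radar_config, config$radar))
  if (is.null(frames)) {
    motion <- stage("motion-model",
                    do.call(chest_motion,
                            c(config$motion, list(seed = config$seed))))
    frames <- stage("simulate",
                    simulate_frames(motion, radar, config$simulate$duration))
    stage("write-frames", write_frames(frames, file.path(out_dir, "frames.csv")))
  }
  fspec <- stage("filter-spec", do.call(filter_spec, config$filter))
  extraction <- stage("extract-rpm",
    extract_rpm(frames, fspec,
                max_breaths_per_min = config$peaks$max_breaths_per_min,
                prominence_factor = config$peaks$prominence_factor))
  write_series_csv(extraction$auc, file.path(out_dir, "auc_series.csv"))
  write_series_csv(extraction$spectrum, file.path(out_dir, "spectrum.csv"))
  write_series_csv(extraction$respiration, file.path(out_dir, "respiration.csv"))
  write_series_csv(tidy(extraction$result), file.path(out_dir, "rpm.csv"))

  cohort <- stage("cohort",
                  generate_cohort(do.call(cohort_spec,
                                          c(config$cohort,
                                            list(seed = child_seed(config$seed, 1))))))
  write_series_csv(cohort, file.path(out_dir, "cohort.csv"))
  benchmark <- stage("benchmark",
    run_benchmark(cohort, seed = as.integer(child_seed(config$seed, 2)),
                  train_fraction = config$protocol$train_fraction,
                  n_folds = config$protocol$n_folds,
                  tune = config$protocol$tune))
  write_series_csv(benchmark, file.path(out_dir, "benchmark.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("respirad")),
    seed = config$seed,
    cohort_seed = child_seed(config$seed, 1),
    benchmark_seed = child_seed(config$seed, 2),
    rpm = extraction$result$rpm,
    artifacts = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(extraction = extraction, cohort = cohort,
                 benchmark = benchmark, manifest = manifest))
}
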