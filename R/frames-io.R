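#' Write and read radar frame matrices
#'
#' Frame matrices are stored as a self-describing text file: comment lines
#' prefixed `#` carry the radar configuration
#' (`frame_rate`, `n_bins`, `bin_length`, `range_start`, `effective_range`,
#' optionally `seed`), followed by a comma-separated table with one row per
#' frame: the frame counter, then one amplitude per bin. Round-trips are exact
#' for counters and exact at the stored precision (17 significant digits,
#' i.e. value-exact for doubles) for amplitudes.
#'
#' @param frames A [frame_matrix()].
#' @param path File path to write to / read from.
#'
#' @return `write_frames()` returns `path` invisibly; `read_frames()` returns
#'   a [frame_matrix()].
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "frame_matrix"))
  cfg <- frames$config
  hdr <- c(
    sprintf("# frame_rate: %.17g", cfg$frame_rate),
    sprintf("# n_bins: %d", cfg$n_bins),
    sprintf("# bin_length: %.17g", cfg$bin_length),
    sprintf("# range_start: %.17g", cfg$range_start),
    sprintf("# effective_range: %.17g %.17g",
            cfg$effective_range[1], cfg$effective_range[2]),
    if (!is.null(frames$seed)) sprintf("# seed: %d", frames$seed),
    paste(c("counter", sprintf("bin_%03d", seq_len(cfg$n_bins) - 1)),
          collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  body <- cbind(frames$frame_counters, frames$amplitudes)
  utils::write.table(format(body, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) {
    abort_respirad(sprintf("frame file '%s' does not exist.", path),
                   "respirad_format_error")
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (length(lines) == 0 || length(hdr) == 0) {
    abort_respirad(sprintf("frame file '%s' is empty or has no header.", path),
                   "respirad_format_error")
  }
  get_field <- function(name, required = TRUE) {
    m <- hdr[startsWith(hdr, paste0("# ", name, ":"))]
    if (length(m) == 0) {
      if (required) {
        abort_respirad(sprintf("frame file header is missing field '%s'.", name),
                       "respirad_format_error")
      }
      return(NULL)
    }
    as.numeric(strsplit(trimws(sub(".*?:", "", m[1])), "\\s+")[[1]])
  }
  cfg <- radar_config(frame_rate = get_field("frame_rate"),
                      n_bins = get_field("n_bins"),
                      bin_length = get_field("bin_length"),
                      range_start = get_field("range_start"),
                      effective_range = get_field("effective_range"))
  seed <- get_field("seed", required = FALSE)
  body_lines <- lines[!startsWith(lines, "#")]
  body_lines <- body_lines[nzchar(trimws(body_lines))]
  if (length(body_lines) <= 1) {
    abort_respirad(sprintf("frame file '%s' contains no frame rows.", path),
                   "respirad_format_error")
  }
  body <- utils::read.csv(textConnection(body_lines), header = TRUE)
  if (ncol(body) - 1 != cfg$n_bins) {
    abort_respirad(
      sprintf("frame file has %d amplitude columns but header n_bins is %d.",
              ncol(body) - 1, cfg$n_bins),
      "respirad_format_error")
  }
  frame_matrix(as.matrix(body[, -1, drop = FALSE]),
               frame_counters = body[[1]], config = cfg,
               seed = if (is.null(seed)) NULL else as.integer(seed))
}
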