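# internal helpers

abort_respirad <- function(msg, class) {
  rlang::abort(msg, class = c(class, "respirad_error"))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is_number(x)) {
    abort_respirad(sprintf("`%s` must be a single finite number.", name),
                   "respirad_config_error")
  }
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max) {
    abort_respirad(
      sprintf("`%s` = %s is outside its valid range %s%s, %s].",
              name, format(x), if (strict_min) "(" else "[",
              format(min), format(max)),
      "respirad_config_error")
  }
  x
}

# round-half-up (Tables report RPM as integers; round() would round half to even)
round_half_up <- function(x) floor(x + 0.5)

# derive a reproducible child seed from a base seed, kept below 2^31
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 1000 + offset) %% 2147483647
}
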