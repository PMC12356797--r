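# Internal argument checking helpers.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_probability <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single numeric probability", name)
  }
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!lo_ok || !hi_ok) stopf("`%s` = %g is outside its admissible range", name, x)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

check_binary <- function(x, name) {
  bad <- !is.na(x) & !(x %in% c(0, 1))
  if (any(bad)) {
    stopf("`%s` must contain only 0/1 values (offending value: %s)",
          name, format(x[bad][1]))
  }
  invisible(x)
}

check_score_range <- function(x, name = "ai_score") {
  bad <- !is.na(x) & (x < 0 | x > 100)
  if (any(bad)) {
    stopf("`%s` must lie in [0, 100] (offending value: %s)", name,
          format(x[bad][1]))
  }
  invisible(x)
}

# Derive a valid 32-bit seed deterministically from a base seed and a label.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}
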