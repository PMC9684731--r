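# internal helpers: error classes, seeding, numerical utilities

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "mazephys_config_error", ...)
}

abort_data <- function(msg, ...) {
  rlang::abort(msg, class = "mazephys_data_error", ...)
}

abort_insufficient <- function(msg, ...) {
  rlang::abort(msg, class = "mazephys_insufficient_data_error", ...)
}

# run `code` under a local RNG state when a seed is given, untouched otherwise
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# derive a reproducible child seed; stays inside 32-bit integer range
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(offset) * 7919 + 13) %% 2147483647)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    abort_config(sprintf("`%s` must be > %g", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort_config(sprintf("`%s` must be >= %g", name, lower))
  }
  if (x > upper) {
    abort_config(sprintf("`%s` must be <= %g", name, upper))
  }
  invisible(x)
}

# trapezoidal rule on an (x, y) grid
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
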