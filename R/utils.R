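# internal validation helpers; classed conditions so callers can distinguish
# bad input from numerical failure

stop_validation <- function(msg, ...) {
  rlang::abort(msg, class = "rhozero_validation_error", ...)
}

check_finite_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    stop_validation(sprintf("`%s` must be in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

check_times <- function(times, strictly_increasing = FALSE) {
  if (!is.numeric(times) || length(times) == 0L || anyNA(times) ||
      any(!is.finite(times))) {
    stop_validation("`times` must be finite numeric values.")
  }
  if (any(times < 0)) {
    stop_validation("`times` must be non-negative.")
  }
  if (strictly_increasing && any(diff(times) <= 0)) {
    stop_validation("`times` must be strictly increasing.")
  }
  invisible(times)
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_validation(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# run `expr` under a fixed seed without touching the caller's RNG stream;
# seed = NULL uses (and advances) the current stream
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# derive reproducible stage sub-seeds from one global seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
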