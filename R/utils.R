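#' @importFrom rlang abort warn .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom tibble tibble as_tibble
#' @importFrom stats fft median sd qt pt pnorm pchisq rnorm runif approx
NULL

# shared argument checks -------------------------------------------------

check_numeric_series <- function(x, arg = deparse(substitute(x)),
                                 min_len = 1L, finite = TRUE) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric vector.", arg), class = "ccpulse_type_error")
  }
  if (length(x) < min_len) {
    abort(sprintf("`%s` must have at least %d samples (got %d).",
                  arg, min_len, length(x)),
          class = "ccpulse_length_error")
  }
  if (finite && !all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite samples.", arg),
          class = "ccpulse_data_error")
  }
  invisible(x)
}

check_sample_rate <- function(sample_rate_hz) {
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    abort("`sample_rate_hz` must be a single positive number.",
          class = "ccpulse_config_error")
  }
  invisible(sample_rate_hz)
}

# Evaluate `expr` under a fixed RNG state when `seed` is given, without
# disturbing the caller's stream; with seed = NULL the current stream is used
# (so outer set.seed() still yields reproducible results).
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(seed, expr)
  }
}

`%||%` <- rlang::`%||%`
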