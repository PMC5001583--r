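#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise
#'   ungroup left_join n
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbeta rbinom rnorm runif setNames
NULL

# round half away from zero; base round() is banker's rounding, reported
# overlap percentages follow the usual "31%"-style half-up convention
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  if (strict && x <= min) abort(sprintf("`%s` must be > %s", name, min))
  if (!strict && x < min) abort(sprintf("`%s` must be >= %s", name, min))
  invisible(x)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
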