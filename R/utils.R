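#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor median pnorm pt quantile rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Per-stage seed derivation: every stochastic stage draws its own seed from
# the single run seed so stages stay reproducible independently of each
# other. Offsets are fixed constants; results stay below 2^31 - 1.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647L)
}

# run length encoding as a tibble (value, length)
run_lengths <- function(x) {
  r <- rle(as.vector(x))
  tibble(value = r$values, length = r$lengths)
}

assert_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower) {
    abort(sprintf("`%s` must be a single number >= %s", name, lower))
  }
  invisible(x)
}

# z-score that maps a zero-variance vector to all zeros instead of NaN
safe_z <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
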