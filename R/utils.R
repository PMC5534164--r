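#' Round half away from zero to integer
#'
#' Commercial ("round half up") rounding used for every printed percentage
#' and count in the report tables, where `round()`'s banker's rounding would
#' disagree (e.g. `round(2.5)` is 2 but `round_half_up(2.5)` is 3).
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @examples
#' round_half_up(c(20.6, 15.2, 5.2, 1.6, 2.0))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage seeds so that a
#' single stage can be rerun in isolation with the same stream. The result
#' stays inside the 32-bit integer range R requires of `set.seed()`.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage label.
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  # cheap string hash, stable across platforms
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master_seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# integer percent of a count over a base, round-half-up; 0 when base is 0
pct_int <- function(n, base) {
  ifelse(base > 0, round_half_up(100 * n / base), 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
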