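# Small shared helpers. All user-facing randomness goes through with_seed() so
# that every generator accepts an explicit seed without clobbering the caller's
# RNG stream.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state. With `seed = NULL` the code is evaluated
#' against the ambient RNG stream, which is how pipeline drivers thread one
#' replicate seed through several stochastic stages.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Deterministic rounding used for split sizes and the low/high QTL count
#' split, where `base::round()`'s round-half-to-even rule would be surprising
#' (e.g. a one-tenth test split of 1368 animals must give 137).
#'
#' @param x Numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @export
round_half_up <- function(x) {
  floor(abs(x) + 0.5) * sign(x)
}

#' Population variance (denominator n)
#'
#' Variance with the population convention, used wherever a simulated quantity
#' must hit a target variance exactly in-sample (e.g. Var(TBV) = 100 h^2).
#'
#' @param x Numeric vector.
#' @return Mean squared deviation from the mean.
#' @export
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

# Weighted sampling without replacement via exponential keys
# (Efraimidis-Spirakis); O(n log n) regardless of the draw count, unlike
# base::sample(prob = ) which degrades badly at array scale.
weighted_sample_norep <- function(x, size, w) {
  stopifnot(length(x) == length(w), size <= length(x), all(w >= 0))
  if (sum(w > 0) < size) stop("fewer positive-weight items than `size`", call. = FALSE)
  keys <- rexp(length(x)) / w  # w == 0 -> Inf key, never selected
  x[order(keys)[seq_len(size)]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
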