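#' Adjusted coefficient of determination
#'
#' Penalizes R-squared for model size: \eqn{1 - (1-R^2)(n-1)/(n-p-1)}.
#' Each evaluation set uses its own \code{n}.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations in the evaluation set.
#' @param p Number of predictors.
#' @return Adjusted R-squared (may be negative).
#' @export
adjusted_r2 <- function(r2, n, p) {
  stopifnot(n > p + 1)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' R-squared of predictions against observations
#'
#' \eqn{1 - SS_{res}/SS_{tot}} with the total sum of squares about the
#' observed mean of the same set.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return R-squared (negative when predictions do worse than the mean).
#' @export
prediction_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values are constant; R-squared undefined")
  1 - sum((observed - predicted)^2) / sst
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions never perturb user randomness.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Round half away from zero (so 2.5 -> 3); used for percentile bin bounds.
round_half_up <- function(x) floor(x + 0.5)

# Derive a stream of sub-seeds from one master seed, kept under 2^31.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647
}
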