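#' Half-up rounding
#'
#' Rounds halves away from zero (0.005 -> 0.01 at 2 decimals), matching the
#' report convention; base `round()` uses banker's rounding, which differs
#' at exact ties.
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-12) / s
}

# Multivariate normal draws via the Cholesky factor (deterministic given
# the RNG state).
rmvnorm_chol <- function(n, Sigma) {
  p <- nrow(Sigma)
  L <- chol(Sigma)
  matrix(stats::rnorm(n * p), n, p) %*% L
}
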