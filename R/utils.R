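# Internal numerical helpers shared across modules.

# x * log(x) with the 0*log(0) = 0 convention.
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}

# Flux-weighted log term a * log(a / b) used by entropy production sums.
# Conventions (matching the master-equation formulas):
#   a == 0 and b == 0 -> 0 (absent link)
#   a  > 0 and b == 0 -> +Inf (unidirectional link, genuinely divergent)
#   a == 0 and b  > 0 -> 0 (the flux prefactor vanishes)
flux_log <- function(a, b) {
  out <- numeric(length(a))
  both <- a > 0 & b > 0
  out[both] <- a[both] * log(a[both] / b[both])
  out[a > 0 & b == 0] <- Inf
  out
}

assert_prob <- function(p, tol = 1e-8, arg = "p") {
  if (any(p < -tol)) {
    abort(sprintf("`%s` must be non-negative.", arg))
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.12g).", arg, sum(p)))
  }
  invisible(p)
}

assert_positive <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", arg))
  }
  invisible(x)
}

# Trapezoid weights for a (possibly non-uniform) grid.
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

# Deterministic per-stream seeds derived from one user seed; keeps every
# trajectory's noise stream independent of how many trajectories are run.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  base <- as.double(seed %% 2147483647L)
  (as.double(base) + 48271 * seq_len(n)) %% 2147483647
}

#' Convert an entropy or information value from nats to bits
#'
#' All entropies and information measures in the package are reported in nats
#' (natural log). This helper rescales to bits.
#'
#' @param x Value(s) in nats.
#' @return Value(s) in bits.
#' @export
#' @examples
#' nats_to_bits(log(2)) # 1 bit
nats_to_bits <- function(x) x / log(2)
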