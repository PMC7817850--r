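#' Numerical conventions for categorical distributions
#'
#' All probability vectors handled by the package are finite, non-negative and
#' sum to one within `1e-9`. Before any logarithm is taken, probabilities are
#' floored at `1e-16` so that degenerate (one-hot) likelihood columns never
#' produce `-Inf`; the floor is small enough not to distort any reported
#' quantity at the package's stated tolerances.
#'
#' @name categorical-conventions
#' @keywords internal
NULL

# floor applied before every log; see categorical-conventions
.LOG_FLOOR <- 1e-16

# sum-to-one tolerance for a valid categorical
.CAT_TOL <- 1e-9

#' Floor a non-negative vector and normalize it to a categorical
#'
#' Adds `epsilon` to every entry and divides by the total. This is the shared
#' numerical primitive used to keep log-domain computations finite when
#' distributions have exact zeros.
#'
#' @param v Non-negative numeric vector.
#' @param epsilon Non-negative scalar added to every entry before
#'   normalization. Default `1e-16`.
#' @return A numeric probability vector of the same length summing to one.
#' @examples
#' floor_and_normalize(c(3, 1))          # 0.75 0.25
#' floor_and_normalize(c(0, 0), 1e-16)   # 0.5 0.5
#' @export
floor_and_normalize <- function(v, epsilon = .LOG_FLOOR) {
  stopifnot(is.numeric(v), length(v) >= 1L, all(is.finite(v)))
  if (any(v < 0)) stop("floor_and_normalize: negative entries", call. = FALSE)
  if (epsilon < 0) stop("floor_and_normalize: epsilon must be >= 0", call. = FALSE)
  w <- v + epsilon
  s <- sum(w)
  if (s <= 0) {
    stop("floor_and_normalize: all-zero vector with epsilon = 0", call. = FALSE)
  }
  w / s
}

# log with the package-wide floor; never returns -Inf for p >= 0
safe_log <- function(p) log(pmax(p, .LOG_FLOOR))

# TRUE iff v is a valid categorical (non-negative, sums to 1 within tol)
is_categorical <- function(v, tol = .CAT_TOL) {
  is.numeric(v) && length(v) >= 1L && all(is.finite(v)) &&
    all(v >= -tol) && abs(sum(v) - 1) <= tol
}

# assert helper used throughout; returns v invisibly
assert_categorical <- function(v, what = "vector") {
  if (!is_categorical(v)) {
    stop(sprintf("%s is not a valid categorical distribution", what),
         call. = FALSE)
  }
  invisible(v)
}

#' Softmax (normalized exponential)
#'
#' Converts a vector of log-weights into a categorical distribution,
#' subtracting the maximum first for numerical stability.
#'
#' @param x Numeric vector of log-weights (nats).
#' @return Probability vector of the same length.
#' @export
softmax <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)))
  e <- exp(x - max(x))
  e / sum(e)
}

#' Kullback-Leibler divergence between two categoricals
#'
#' Computes `sum(p * (log p - log q))` in nats with the package flooring.
#' Non-negative up to floating-point error.
#'
#' @param p,q Probability vectors of equal length.
#' @return Scalar divergence in nats.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(p * (safe_log(p) - safe_log(q)))
}

# total variation distance between two categoricals
total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# draw a flat-Dirichlet vector using the current RNG stream
rdirichlet_flat <- function(n) {
  g <- stats::rgamma(n, shape = 1, rate = 1)
  g / sum(g)
}

# sample one index from a categorical using the current RNG stream
sample_categorical <- function(p) {
  sample.int(length(p), size = 1L, prob = p)
}
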