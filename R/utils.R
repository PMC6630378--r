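#' @keywords internal
#' @useDynLib pedpk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Numerically stable log(sum(exp(x)))
#'
#' Used to combine per-dose concentration contributions on the log scale so
#' that predictions stay finite even when individual terms underflow.
#'
#' @param x numeric vector (may contain -Inf for zero contributions)
#' @return scalar log-sum-exp
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp over a matrix (one row per observation time).
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}

# log(exp(a) - exp(b)) for a > b, stable when a - b is small or large.
logdiffexp <- function(a, b) {
  a + log1p(-exp(pmax(b - a, -745)))
}

#' Draw from a truncated normal by inverse-CDF
#'
#' Exact and reproducible (one uniform per draw), no rejection loop.
#'
#' @param n number of draws
#' @param mean,sd moments of the parent normal
#' @param lower,upper truncation bounds
#' @return numeric vector of length `n` inside `[lower, upper]`
#' @export
rtruncnorm_icdf <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (lower >= upper) stop("infeasible truncation: lower >= upper")
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n)
  q <- stats::qnorm(plo + u * (phi - plo), mean, sd)
  pmin(pmax(q, lower), upper)
}

# Symmetric (eigen) inverse square root of a positive-definite matrix.
# Eigen root rather than Cholesky so the result is invariant to row order.
sym_inv_sqrt <- function(m, ridge = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- e$values
  if (any(vals < ridge)) vals <- vals + ridge
  e$vectors %*% diag(1 / sqrt(vals), nrow = length(vals)) %*% t(e$vectors)
}
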