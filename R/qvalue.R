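# Storey q-values: null-proportion estimation over a lambda grid with
# spline smoothing, and the step-down q-value transform.

validate_pvalues <- function(pvalues) {
  if (length(pvalues) == 0L) gxe_stop("empty p-value vector")
  if (!is.numeric(pvalues) || any(!is.finite(pvalues))) {
    gxe_stop("p-values must be finite numbers")
  }
  if (any(pvalues <= 0 | pvalues > 1)) {
    gxe_stop("p-values must lie in (0, 1]")
  }
  invisible(pvalues)
}

#' Estimate the proportion of true nulls from a p-value distribution
#'
#' Computes `pi0(lambda) = #(p > lambda) / (N * (1 - lambda))` over a grid of
#' tuning values, smooths the curve with a cubic smoothing spline (3 df), and
#' reads off the estimate at the largest `lambda`, where the alternative
#' contributes least. The estimate is clamped to `[1e-8, 1]` so downstream
#' q-values are never exactly zero. For short vectors (fewer than 100
#' p-values, where the grid estimates are too noisy to smooth) a single fixed
#' `lambda = 0.5` is used instead, with a warning.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param lambda_grid Grid of tuning values in (0, 1); default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @return The estimated null proportion, a single number in (0, 1].
#' @export
estimate_pi0 <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  validate_pvalues(pvalues)
  if (any(lambda_grid <= 0 | lambda_grid >= 1)) {
    gxe_stop("lambda_grid values must lie in (0, 1)")
  }
  n <- length(pvalues)
  if (n < 100L) {
    warning("fewer than 100 p-values: using fixed lambda = 0.5 for pi0")
    lambda_grid <- 0.5
  }
  lambda_grid <- sort(unique(lambda_grid))
  pi0_lambda <- vapply(lambda_grid,
                       function(l) mean(pvalues > l) / (1 - l), numeric(1))
  pi0 <- if (length(lambda_grid) >= 4L) {
    fit <- stats::smooth.spline(lambda_grid, pi0_lambda, df = 3)
    stats::predict(fit, x = max(lambda_grid))$y
  } else {
    pi0_lambda[length(pi0_lambda)]
  }
  min(max(pi0, 1e-8), 1)
}

#' Storey q-values
#'
#' Transforms p-values into q-values: with `p_(1) <= ... <= p_(N)` sorted,
#' `q_(i) = min_{j >= i} pi0 * p_(j) * N / j`, mapped back to the input
#' order and capped at 1. With `pi0 = 1` this is exactly the
#' Benjamini-Hochberg adjustment.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param pi0 Null proportion; estimated via [estimate_pi0()] when `NULL`.
#' @return An object of class `"qvalue_result"`: list with `qvalues` (same
#'   length and order as the input) and `pi0`.
#' @examples
#' r <- compute_qvalues(runif(500))
#' r$pi0
#' @export
compute_qvalues <- function(pvalues, pi0 = NULL) {
  validate_pvalues(pvalues)
  if (is.null(pi0)) pi0 <- estimate_pi0(pvalues)
  if (!is_number(pi0) || pi0 <= 0 || pi0 > 1) {
    gxe_stop("pi0 must lie in (0, 1]")
  }
  n <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- pi0 * pvalues[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- pmin(q_sorted, 1)[order(o)]
  structure(list(qvalues = q, pi0 = pi0), class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat(sprintf("qvalue_result: %d p-values, pi0 = %.4f, %d with q < 0.05\n",
              length(x$qvalues), x$pi0, sum(x$qvalues < 0.05)))
  invisible(x)
}
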