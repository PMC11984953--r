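# Internal helpers shared across modules.

# Typed errors so callers (and tests) can distinguish failure modes.
gxe_stop <- function(msg, class = "gxe_invalid_input", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "gxe_error")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Symmetry + eigenvalue check; tolerance relative to the largest entry.
check_psd <- function(m, name = "covariance") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    gxe_stop(sprintf("%s must be a square matrix", name))
  }
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    gxe_stop(sprintf("%s must be symmetric", name), "gxe_not_psd")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(1, abs(ev[1L]))
  if (min(ev) < -tol) {
    gxe_stop(sprintf("%s is not positive semidefinite", name), "gxe_not_psd")
  }
  invisible(TRUE)
}

# Draw from N(mean, cov) allowing rank-deficient (PSD) covariance, as arises
# for perfectly correlated effect components. Eigen-based square root.
rmvn_psd <- function(n, mean, cov) {
  d <- length(mean)
  e <- eigen(cov, symmetric = TRUE)
  # zero out numerically-null eigenvalues so rank-deficient components (e.g.
  # perfectly correlated effects) reproduce their affine structure exactly
  vals <- pmax(e$values, 0)
  vals[vals < 1e-12 * max(vals, 0)] <- 0
  rt <- e$vectors %*% (sqrt(vals) * t(e$vectors))
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% rt, 2L, mean, `+`)
}

# Seed helper: set.seed only when a seed was supplied.
maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is_number(seed)) gxe_stop("seed must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
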