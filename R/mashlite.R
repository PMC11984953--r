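# Lightweight empirical-Bayes multivariate shrinkage ("mash-lite"): the
# effects of each variant in two contexts are modelled as drawn from a
# mixture of zero-centered bivariate normal priors with fixed covariance
# structures (including the null matrix); mixture weights are fit by
# maximum likelihood via EM against the marginal likelihood of the noisy
# estimates, and posterior means shrink estimates toward the covariance
# patterns common across the genome.

#' Canonical grid of 2x2 prior covariance components
#'
#' For each scale `s` the grid contains: equal effects `[[s, s], [s, s]]`,
#' context-A-specific `[[s, 0], [0, 0]]`, context-B-specific, independent
#' `[[s, 0], [0, s]]`, and amplification components
#' `[[s a^2, s a], [s a, s]]` for each factor `a` (perfect correlation, sd
#' ratio `a`). The zero matrix is always included to induce additional
#' shrinkage of null effects.
#'
#' @param scales Positive variance scales; default 1.
#' @param amp_factors Amplification sd ratios; default
#'   `c(1.5, 2, 1/1.5, 1/2)`.
#' @return A named list of 2x2 PSD matrices of class `"covariance_grid"`,
#'   first element `null`.
#' @export
build_canonical_grid <- function(scales = 1,
                                 amp_factors = c(1.5, 2, 1 / 1.5, 1 / 2)) {
  if (any(scales <= 0)) gxe_stop("scales must be positive")
  comps <- list(null = matrix(0, 2, 2))
  for (s in scales) {
    tag <- function(name) sprintf("%s_s%g", name, s)
    comps[[tag("equal")]] <- matrix(s, 2, 2)
    comps[[tag("a_only")]] <- matrix(c(s, 0, 0, 0), 2)
    comps[[tag("b_only")]] <- matrix(c(0, 0, 0, s), 2)
    comps[[tag("indep")]] <- diag(c(s, s))
    for (a in amp_factors) {
      comps[[sprintf("amp%g_s%g", a, s)]] <-
        s * matrix(c(a^2, a, a, 1), 2)
    }
  }
  for (nm in names(comps)) check_psd(comps[[nm]], nm)
  structure(comps, class = "covariance_grid")
}

# Log marginal likelihood of each row of B under N(0, U + diag(S2_j)),
# vectorised over rows via the closed-form 2x2 determinant/inverse.
loglik_component <- function(b1, b2, s2a, s2b, U) {
  v11 <- U[1, 1] + s2a
  v22 <- U[2, 2] + s2b
  v12 <- U[1, 2]
  det <- v11 * v22 - v12^2
  quad <- (v22 * b1^2 - 2 * v12 * b1 * b2 + v11 * b2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * quad
}

panel_loglik_matrix <- function(estimates, ses, grid) {
  estimates <- as.matrix(estimates)
  ses <- as.matrix(ses)
  if (!all(dim(estimates) == dim(ses)) || ncol(estimates) != 2L) {
    gxe_stop("estimates and ses must be J x 2 matrices of equal dimension")
  }
  if (any(!is.finite(estimates)) || any(!is.finite(ses)) || any(ses <= 0)) {
    gxe_stop("estimates must be finite and ses strictly positive")
  }
  s2a <- ses[, 1]^2
  s2b <- ses[, 2]^2
  L <- vapply(grid, function(U) {
    loglik_component(estimates[, 1], estimates[, 2], s2a, s2b, U)
  }, numeric(nrow(estimates)))
  if (nrow(estimates) == 1L) L <- matrix(L, nrow = 1L)
  L
}

#' Fit mixture weights over a covariance grid by EM
#'
#' Maximises the marginal log-likelihood
#' `sum_j log sum_k pi_k N(betahat_j; 0, U_k + S_j)` over the mixture
#' weights, with `S_j = diag(se_j^2)` the known noise covariance of variant
#' `j`. Standard EM: responsibilities in the E-step, mean responsibility as
#' the new weight in the M-step; the log-likelihood is non-decreasing and
#' iteration stops when its relative gain falls below `tol`.
#'
#' @param estimates,ses J x 2 matrices (contexts in columns).
#' @param grid A [build_canonical_grid()] (or any named list of 2x2 PSD
#'   matrices).
#' @param tol Relative log-likelihood tolerance; default 1e-6.
#' @param max_iter Iteration cap; default 1000.
#' @return An object of class `"mixture_fit"`: list with `weights` (named,
#'   summing to 1), `log_likelihood` (trace, one entry per iteration) and
#'   `n_iter`.
#' @export
fit_mixture_em <- function(estimates, ses, grid, tol = 1e-6, max_iter = 1000) {
  L <- panel_loglik_matrix(estimates, ses, grid)
  bad <- which(!is.finite(rowSums(L)))
  if (length(bad)) {
    gxe_stop(sprintf("non-finite likelihood for variant row %d", bad[1L]),
             "gxe_bad_likelihood")
  }
  k <- ncol(L)
  pi_k <- rep(1 / k, k)
  trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    lw <- sweep(L, 2L, log(pi_k), `+`)
    mrow <- apply(lw, 1L, max)
    lse <- mrow + log(rowSums(exp(lw - mrow)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    gamma <- exp(lw - lse)
    pi_k <- colMeans(gamma)
    if (is.finite(ll_prev) && (ll - ll_prev) < tol * abs(ll)) break
    ll_prev <- ll
  }
  names(pi_k) <- colnames(L) <- names(grid)
  structure(list(weights = pi_k, log_likelihood = trace, n_iter = length(trace)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  top <- sort(x$weights, decreasing = TRUE)
  top <- top[top > 0.01]
  cat(sprintf("mixture_fit: %d iterations, log-likelihood %.3f\n",
              x$n_iter, x$log_likelihood[x$n_iter]))
  cat("  weights > 1%:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior effect estimates under the fitted mixture prior
#'
#' Per variant, component responsibilities are
#' `gamma_jk \propto pi_k N(betahat_j; 0, U_k + S_j)`; the component
#' posterior for the true effect is normal with mean
#' `U_k (U_k + S_j)^{-1} betahat_j` and covariance
#' `U_k - U_k (U_k + S_j)^{-1} U_k`, and the reported posterior mean and
#' standard deviation are those of the responsibility-weighted mixture.
#'
#' @param estimates,ses J x 2 matrices.
#' @param grid The covariance grid used in fitting.
#' @param fit A [fit_mixture_em()] result.
#' @return An object of class `"posterior_panel"`: list with
#'   `posterior_means` (J x 2), `posterior_sds` (J x 2), `responsibilities`
#'   (J x K, rows summing to 1) and `top_component` (label of the largest
#'   responsibility per variant).
#' @export
posterior_means <- function(estimates, ses, grid, fit) {
  if (!inherits(fit, "mixture_fit")) gxe_stop("expected a mixture_fit")
  estimates <- as.matrix(estimates)
  ses <- as.matrix(ses)
  L <- panel_loglik_matrix(estimates, ses, grid)
  lw <- sweep(L, 2L, log(pmax(fit$weights, 1e-300)), `+`)
  mrow <- apply(lw, 1L, max)
  gamma <- exp(lw - (mrow + log(rowSums(exp(lw - mrow)))))

  j <- nrow(estimates)
  s2a <- ses[, 1]^2
  s2b <- ses[, 2]^2
  b1 <- estimates[, 1]
  b2 <- estimates[, 2]
  pm <- matrix(0, j, 2)
  m2 <- matrix(0, j, 2)  # second moments
  for (k in seq_along(grid)) {
    U <- grid[[k]]
    v11 <- U[1, 1] + s2a
    v22 <- U[2, 2] + s2b
    v12 <- U[1, 2]
    det <- v11 * v22 - v12^2
    # w = (U + S)^{-1} betahat
    w1 <- (v22 * b1 - v12 * b2) / det
    w2 <- (-v12 * b1 + v11 * b2) / det
    mu1 <- U[1, 1] * w1 + U[1, 2] * w2
    mu2 <- U[1, 2] * w1 + U[2, 2] * w2
    # T = U (U + S)^{-1}; Sigma = U - T U (diagonal entries only)
    t11 <- (U[1, 1] * v22 - U[1, 2] * v12) / det
    t12 <- (-U[1, 1] * v12 + U[1, 2] * v11) / det
    t21 <- (U[1, 2] * v22 - U[2, 2] * v12) / det
    t22 <- (-U[1, 2] * v12 + U[2, 2] * v11) / det
    sig11 <- U[1, 1] - (t11 * U[1, 1] + t12 * U[1, 2])
    sig22 <- U[2, 2] - (t21 * U[1, 2] + t22 * U[2, 2])
    g <- gamma[, k]
    pm[, 1] <- pm[, 1] + g * mu1
    pm[, 2] <- pm[, 2] + g * mu2
    m2[, 1] <- m2[, 1] + g * (pmax(sig11, 0) + mu1^2)
    m2[, 2] <- m2[, 2] + g * (pmax(sig22, 0) + mu2^2)
  }
  psd <- sqrt(pmax(m2 - pm^2, 0))
  colnames(pm) <- colnames(psd) <- c("A", "B")
  structure(
    list(posterior_means = pm, posterior_sds = psd, responsibilities = gamma,
         top_component = names(grid)[max.col(gamma)]),
    class = "posterior_panel"
  )
}

# Data-driven variance scales for the default grid, ashr-style: a geometric
# ladder from well below the measurement noise to twice the largest
# noise-corrected signal.
auto_scales <- function(estimates, ses, mult = 4) {
  lo <- (min(ses) / 10)^2
  hi <- 4 * max(max(estimates^2 - ses^2), lo)
  n <- max(1L, ceiling(log(hi / lo) / log(mult)))
  lo * mult^(0:n)
}

#' One-call empirical-Bayes shrinkage of a two-context effect panel
#'
#' Builds a canonical grid over data-driven scales (unless one is given),
#' fits the mixture weights by EM and returns the posterior panel together
#' with the fit.
#'
#' @param estimates,ses J x 2 matrices of effect estimates and standard
#'   errors.
#' @param grid Optional covariance grid; defaults to
#'   [build_canonical_grid()] over [auto_scales()].
#' @param ... Passed to [fit_mixture_em()].
#' @return A list of class `"mash_lite"` with elements `fit`, `grid` and
#'   the fields of the [posterior_means()] result.
#' @export
mash_lite <- function(estimates, ses, grid = NULL, ...) {
  estimates <- as.matrix(estimates)
  ses <- as.matrix(ses)
  if (is.null(grid)) {
    grid <- build_canonical_grid(auto_scales(estimates, ses))
  }
  fit <- fit_mixture_em(estimates, ses, grid, ...)
  post <- posterior_means(estimates, ses, grid, fit)
  structure(c(list(fit = fit, grid = grid), unclass(post)),
            class = "mash_lite")
}

#' @export
print.mash_lite <- function(x, ...) {
  cat(sprintf("mash_lite: %d variants, %d components\n",
              nrow(x$posterior_means), length(x$grid)))
  print(x$fit)
  invisible(x)
}

#' Univariate empirical-Bayes shrinkage
#'
#' The single-context analogue of [mash_lite()]: a mixture of a point mass
#' at zero and zero-centered normals with variances on `scale_grid`, fit by
#' the same EM, with component posterior mean `s / (s + se^2) * estimate`.
#'
#' @param estimates,ses Numeric vectors.
#' @param scale_grid Positive prior variances; defaults to a data-driven
#'   geometric ladder. The point mass at zero is always included.
#' @return A list with `posterior_mean`, `posterior_sd`, `weights` and
#'   `log_likelihood`.
#' @export
shrink_univariate <- function(estimates, ses, scale_grid = NULL) {
  if (length(estimates) != length(ses)) gxe_stop("length mismatch")
  if (any(!is.finite(estimates)) || any(ses <= 0)) {
    gxe_stop("estimates must be finite and ses positive")
  }
  if (is.null(scale_grid)) {
    lo <- (min(ses) / 10)^2
    hi <- 4 * max(max(estimates^2 - ses^2), lo)
    n <- max(1L, ceiling(log(hi / lo) / log(4)))
    scale_grid <- lo * 4^(0:n)
  }
  if (any(scale_grid <= 0)) gxe_stop("scale_grid must be positive")
  scales <- c(0, scale_grid)
  s2 <- ses^2
  L <- vapply(scales, function(s) {
    stats::dnorm(estimates, 0, sqrt(s + s2), log = TRUE)
  }, numeric(length(estimates)))
  if (length(estimates) == 1L) L <- matrix(L, nrow = 1L)
  k <- ncol(L)
  pi_k <- rep(1 / k, k)
  ll_prev <- -Inf
  trace <- numeric(0)
  for (it in seq_len(1000L)) {
    lw <- sweep(L, 2L, log(pi_k), `+`)
    mrow <- apply(lw, 1L, max)
    lse <- mrow + log(rowSums(exp(lw - mrow)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    gamma <- exp(lw - lse)
    pi_k <- colMeans(gamma)
    if (is.finite(ll_prev) && (ll - ll_prev) < 1e-6 * abs(ll)) break
    ll_prev <- ll
  }
  mu <- vapply(scales, function(s) s / (s + s2) * estimates,
               numeric(length(estimates)))
  vv <- vapply(scales, function(s) s * s2 / (s + s2),
               numeric(length(estimates)))
  if (length(estimates) == 1L) {
    mu <- matrix(mu, nrow = 1L)
    vv <- matrix(vv, nrow = 1L)
  }
  pm <- rowSums(gamma * mu)
  m2 <- rowSums(gamma * (vv + mu^2))
  list(posterior_mean = pm, posterior_sd = sqrt(pmax(m2 - pm^2, 0)),
       weights = stats::setNames(pi_k, paste0("s", signif(scales, 3))),
       log_likelihood = trace)
}

#' Pseudo p-values from posterior summaries
#'
#' `2 * pnorm(-|posterior_mean| / posterior_sd)` — a significance-like
#' ranking statistic for ascertainment from shrunken estimates. A zero
#' posterior sd (complete shrinkage to the point mass) maps to 1.
#'
#' @param posterior_mean,posterior_sd Numeric vectors or matrices.
#' @return Pseudo p-values with the same shape.
#' @export
pseudo_pvalues <- function(posterior_mean, posterior_sd) {
  z <- ifelse(posterior_sd > 0, abs(posterior_mean) / posterior_sd, 0)
  2 * stats::pnorm(-z)
}
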