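# Shared fixture builders: everything is generated in code under a caller-set
# seed; no data files.

# Random polymorphic two-context sample. Resamples genotypes until both
# contexts and the pooled sample are polymorphic.
random_sample <- function(n = 40, m = 40, beta_a = 0.3, beta_b = 0.1,
                          freq_a = 0.3, freq_b = 0.3, sigma_a = 1,
                          sigma_b = 1) {
  repeat {
    ga <- rbinom(n, 2, freq_a)
    gb <- rbinom(m, 2, freq_b)
    if (var(ga) > 0 && var(gb) > 0) break
  }
  ya <- 0.5 + beta_a * ga + rnorm(n, 0, sigma_a)
  yb <- -0.2 + beta_b * gb + rnorm(m, 0, sigma_b)
  stratified_sample(c(ga, gb), c(ya, yb), rep(c("A", "B"), c(n, m)))
}

# Summary-stat table with exactly prescribed columns (helper for screen and
# io tests).
make_records <- function(beta_a, beta_b, se_a, se_b, block_id = NULL,
                         pval_a = NULL) {
  df <- data.frame(
    variant_id = sprintf("v%04d", seq_along(beta_a)),
    beta_a = beta_a, se_a = se_a, beta_b = beta_b, se_b = se_b,
    stringsAsFactors = FALSE
  )
  if (!is.null(pval_a)) df$pval_a <- pval_a
  if (!is.null(block_id)) df$block_id <- block_id
  df
}

# Independent PSD-safe bivariate normal sampler (eigen square root), so tests
# can build rank-deficient truths without touching package internals.
rmvn_psd_for_test <- function(n, cov) {
  e <- eigen(cov, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vals[vals < 1e-12 * max(vals, 1e-300)] <- 0
  z <- matrix(rnorm(n * ncol(cov)), n, ncol(cov))
  z %*% (e$vectors %*% (sqrt(vals) * t(e$vectors)))
}
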