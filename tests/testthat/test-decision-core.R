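# Single-locus estimators, the pooled-weight identity, and all forms of the
# MSE decision rule.

test_that("within-context centering zeroes context means and is idempotent", {
  s <- stratified_sample(c(0, 1, 0, 1), c(1, 3, 5, 5), c("A", "A", "B", "B"))
  cs <- center_within_context(s)
  expect_equal(cs$traits, c(-1, 1, 0, 0))
  expect_equal(cs$genotypes, s$genotypes)
  expect_equal(center_within_context(cs)$traits, cs$traits)

  set.seed(41)
  for (i in 1:5) {
    cs <- center_within_context(random_sample())
    expect_lt(abs(sum(cs$traits[cs$context == "A"])), 1e-12)
    expect_lt(abs(sum(cs$traits[cs$context == "B"])), 1e-12)
  }
  expect_error(stratified_sample(c(0, 1), c(1, 2), c("A", "A")),
               class = "gxe_empty_context")
})

test_that("stratified OLS matches the normal equations and lm()", {
  # perfect fit
  s <- stratified_sample(c(0, 1, 2, 0, 1), c(0, 1, 2, 5, 5),
                         rep(c("A", "B"), c(3, 2)))
  f <- ols_stratified(s)
  expect_equal(f$A$slope, 1)
  expect_equal(f$A$residual_variance, 0)

  set.seed(7)
  for (i in 1:5) {
    s <- random_sample(n = 30, m = 25)
    f <- ols_stratified(s)
    for (ctx in c("A", "B")) {
      ix <- s$context == ctx
      ref <- lm(s$traits[ix] ~ s$genotypes[ix])
      expect_equal(f[[ctx]]$slope, unname(coef(ref)[2]), tolerance = 1e-10)
      expect_equal(f[[ctx]]$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
      expect_equal(f[[ctx]]$se, unname(coef(summary(ref))[2, 2]),
                   tolerance = 1e-10)
    }
  }

  s <- stratified_sample(c(1, 1, 1, 0, 2), c(1, 2, 3, 4, 5),
                         rep(c("A", "B"), c(3, 2)))
  expect_error(ols_stratified(s), class = "gxe_monomorphic")
  expect_error(ols_stratified(s), "context A")
})

test_that("stratified slopes equal the interaction-model slopes", {
  set.seed(13)
  for (i in 1:5) {
    s <- random_sample(n = 35, m = 50, beta_a = 0.5, beta_b = -0.2)
    f <- ols_stratified(s)
    ctx <- factor(s$context)
    ref <- lm(s$traits ~ s$genotypes * ctx)
    slope_a <- unname(coef(ref)["s$genotypes"])
    slope_b <- slope_a + unname(coef(ref)["s$genotypes:ctxB"])
    expect_equal(f$A$slope, slope_a, tolerance = 1e-8)
    expect_equal(f$B$slope, slope_b, tolerance = 1e-8)
  }
})

test_that("additive OLS matches lm() and reduces to either context when contexts coincide", {
  set.seed(5)
  s <- random_sample(n = 40, m = 40)
  add <- ols_additive(s)
  ref <- lm(s$traits ~ s$genotypes)
  expect_equal(add$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(add$se, unname(coef(summary(ref))[2, 2]), tolerance = 1e-10)

  # duplicating one context: pooled slope equals the stratified slope
  g <- rbinom(20, 2, 0.4)
  y <- 0.3 * g + rnorm(20)
  twin <- stratified_sample(c(g, g), c(y, y), rep(c("A", "B"), each = 20))
  expect_equal(ols_additive(twin)$slope, ols_stratified(twin)$A$slope,
               tolerance = 1e-12)
})

test_that("pooled slope is the omega-weighted combination of stratified slopes", {
  set.seed(11)
  for (i in 1:25) {
    s <- center_within_context(
      random_sample(n = sample(10:60, 1), m = sample(10:60, 1),
                    freq_a = runif(1, 0.1, 0.5), freq_b = runif(1, 0.1, 0.5)))
    w <- combination_weights(s)
    f <- ols_stratified(s)
    add <- ols_additive(s)
    combo <- w$omega_a * f$A$slope + w$omega_b * f$B$slope
    expect_lt(abs(add$slope - combo), 1e-10 * max(abs(add$slope), 1e-3))
    # omega ratio equals (n H_A) / (m H_B) (same quantity, so tolerance is
    # only for floating-point evaluation order)
    expect_equal(w$omega_a / w$omega_b,
                 (s$n * w$het_a) / (s$m * w$het_b), tolerance = 1e-12)
    expect_gte(w$omega_a, 0)
    expect_gte(w$omega_b, 0)
  }
})

test_that("combination weights behave under symmetric and 2:1 designs", {
  set.seed(3)
  # equal frequency, equal size: omegas near 1/2
  s <- random_sample(n = 4000, m = 4000, freq_a = 0.3, freq_b = 0.3)
  w <- combination_weights(s)
  expect_equal(w$omega_a, 0.5, tolerance = 0.05)
  expect_equal(w$omega_b, 0.5, tolerance = 0.05)

  # duplicate context-B genotypes twice into A: exactly equal heterozygosity
  gb <- c(rep(0, 6), rep(1, 8), rep(2, 4))
  ga <- c(gb, gb)
  s2 <- stratified_sample(c(ga, gb), rnorm(length(ga) + length(gb)),
                          rep(c("A", "B"), c(length(ga), length(gb))))
  w2 <- combination_weights(s2)
  expect_equal(w2$het_a, w2$het_b, tolerance = 1e-12)
  expect_equal(w2$omega_a / w2$omega_b, 2, tolerance = 1e-12)
  # equal heterozygosity implies the weights sum to one
  expect_equal(w2$omega_a + w2$omega_b, 1, tolerance = 1e-12)
})

test_that("mse_pair reproduces the bias-variance decomposition endpoints", {
  # omega_a = 1 collapses the additive estimator onto the GxE estimator
  d <- mse_pair(decision_input(0.4, -0.2, 0.01, 0.02, omega_a = 1, omega_b = 0))
  expect_equal(d$mse_additive, d$mse_gxe)
  expect_identical(d$preferred, "additive")  # tie resolves to additive

  # equal effects, equal variance: additive wins by pure variance reduction
  d2 <- mse_pair(decision_input(0.3, 0.3, 0.01, 0.01, omega_a = 0.5))
  expect_equal(d2$mse_additive, 0.5 * 0.01)
  expect_identical(d2$preferred, "additive")

  expect_error(decision_input(0, 0, -1, 1, 0.5),
               class = "gxe_nonpositive_variance")
})

test_that("analytic MSEs match Monte-Carlo estimates and verdict signs", {
  # Fixed genotypes; the analytic decision input uses the true residual
  # variances, and the Monte-Carlo oracle simulates the generative model.
  set.seed(23)
  n <- 60
  m <- 40
  ga <- rbinom(n, 2, 0.3)
  gb <- rbinom(m, 2, 0.35)
  reps <- 30000
  points <- list(
    list(beta_a = 0.5, beta_b = -0.1, sa = 1, sb = 1),    # strong GxE
    list(beta_a = 0.2, beta_b = 0.2, sa = 1, sb = 1),     # no GxE
    list(beta_a = 0.35, beta_b = 0.25, sa = 2, sb = 2)    # weak GxE, noisy
  )
  s0 <- stratified_sample(c(ga, gb), rnorm(n + m), rep(c("A", "B"), c(n, m)))
  w <- combination_weights(s0)
  gca <- ga - mean(ga)
  gcb <- gb - mean(gb)
  sxa <- sum(gca^2)
  sxb <- sum(gcb^2)
  for (pt in points) {
    va <- pt$sa^2 / sxa
    vb <- pt$sb^2 / sxb
    dec <- mse_pair(decision_input(pt$beta_a, pt$beta_b, va, vb,
                                   w$omega_a, w$omega_b))
    ya <- matrix(rnorm(reps * n, 0, pt$sa), reps, n) +
      rep(pt$beta_a * ga, each = reps)
    yb <- matrix(rnorm(reps * m, 0, pt$sb), reps, m) +
      rep(pt$beta_b * gb, each = reps)
    bhat_a <- drop(ya %*% gca) / sxa
    bhat_b <- drop(yb %*% gcb) / sxb
    bhat_add <- w$omega_a * bhat_a + w$omega_b * bhat_b
    err_gxe <- (bhat_a - pt$beta_a)^2
    err_add <- (bhat_add - pt$beta_a)^2
    se_gxe <- sd(err_gxe) / sqrt(reps)
    se_add <- sd(err_add) / sqrt(reps)
    expect_lt(abs(mean(err_gxe) - dec$mse_gxe), 3 * se_gxe)
    expect_lt(abs(mean(err_add) - dec$mse_additive), 3 * se_add)
    empirical_margin <- mean(err_add) - mean(err_gxe)
    expect_identical(dec$preferred, if (empirical_margin > 0) "gxe" else "additive")
  }
})

test_that("signal-to-noise threshold matches direct substitution and mse_pair", {
  expect_equal(snr_threshold(0.5, 1), 2)
  expect_equal(snr_threshold(0.5, 3), 0)  # boundary: additive never preferred beyond
  expect_error(snr_threshold(1.2, 1), class = "gxe_invalid_input")

  set.seed(29)
  for (i in 1:100) {
    omega <- runif(1, 0.05, 0.95)
    va <- runif(1, 1e-4, 1e-2)
    vb <- runif(1, 1e-4, 1e-2)
    ba <- rnorm(1, 0, 0.2)
    bb <- rnorm(1, 0, 0.2)
    verdict_mse <- mse_pair(decision_input(ba, bb, va, vb, omega))$preferred
    snr <- (ba - bb)^2 / va
    verdict_snr <- if (snr > snr_threshold(omega, vb / va)) "gxe" else "additive"
    expect_identical(verdict_snr, verdict_mse)
  }
})

test_that("critical noise ratio marks where GxE becomes unconditionally preferred", {
  expect_equal(critical_noise_ratio(0.5), 1 / 3)
  expect_equal(critical_noise_ratio(1e-9), 1, tolerance = 1e-6)
  # for r slightly below r*, the threshold is negative (GxE for any signal)
  for (omega in c(0.2, 0.5, 0.8)) {
    r <- critical_noise_ratio(omega) * 0.99
    expect_lt(snr_threshold(omega, 1 / r), 0)
    r_above <- critical_noise_ratio(omega) * 1.01
    expect_gt(snr_threshold(omega, 1 / r_above), 0)
  }
})

test_that("equal-het equal-noise boundary solves the MSE equality", {
  expect_equal(boundary_equal_het(50, 50, 0.2), 0.02)
  expect_equal(boundary_equal_het(10, 7, 0), 0)
  # at the boundary the margin vanishes (omega_a = n / (n + m))
  for (ratio in c(0.5, 1, 2)) {
    n <- 40
    m <- as.integer(40 * ratio)
    va <- boundary_equal_het(n, m, 0.3)
    d <- mse_pair(decision_input(0.3, 0, va, va, omega_a = n / (n + m),
                                 omega_b = m / (n + m)))
    expect_lt(abs(d$margin), 1e-12)
  }
  # linear in m/n at fixed effect difference
  b <- vapply(c(0.5, 1, 2), function(r) boundary_equal_het(40, 40 * r, 0.3),
              numeric(1))
  expect_equal(b / b[2], c(0.5, 1, 2))
})

test_that("equal frequencies with equal noise always admit a decision boundary", {
  # 1 - omega_a^2 - omega_b^2 = 2nm/(n+m)^2 > 0
  for (nm in list(c(10, 10), c(5, 50), c(99, 1))) {
    wa <- nm[1] / sum(nm)
    wb <- nm[2] / sum(nm)
    expect_equal(1 - wa^2 - wb^2, 2 * prod(nm) / sum(nm)^2, tolerance = 1e-12)
    expect_gt(1 - wa^2 - wb^2, 0)
  }
})
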