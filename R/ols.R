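# Single-locus OLS: stratified (per-context) and pooled (additive) fits,
# and the weights tying the two together.

new_effect_estimate <- function(slope, intercept, sampling_variance,
                                residual_variance, n_used) {
  structure(
    list(slope = slope, intercept = intercept,
         sampling_variance = sampling_variance,
         residual_variance = residual_variance,
         se = sqrt(sampling_variance), n_used = n_used),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("effect_estimate: slope %.6g (se %.6g), n = %d\n",
              x$slope, x$se, x$n_used))
  invisible(x)
}

# Simple-regression workhorse. sampling_variance is the OLS slope variance
# sigma2_hat / Sxx, with sigma2_hat the residual mean square on n - 2 df.
ols_simple <- function(g, y, label) {
  n <- length(g)
  if (n < 2L) {
    gxe_stop(sprintf("context %s has fewer than 2 individuals", label),
             "gxe_too_small")
  }
  gc <- g - mean(g)
  sxx <- sum(gc^2)
  if (sxx == 0) {
    gxe_stop(sprintf("monomorphic genotypes in %s: stratified/pooled OLS is undefined",
                     label), "gxe_monomorphic")
  }
  slope <- sum(gc * y) / sxx
  intercept <- mean(y) - slope * mean(g)
  rss <- sum((y - intercept - slope * g)^2)
  df <- max(n - 2L, 1L)
  resid_var <- rss / df
  new_effect_estimate(slope, intercept, resid_var / sxx, resid_var, n)
}

#' Context-stratified (GxE) OLS fits
#'
#' Fits an ordinary least squares regression of trait on allele count
#' separately in each context. The stratified slopes are unbiased for the
#' context-specific effects; their sampling variance is
#' `residual_variance / sum((g - mean(g))^2)` within the context. The
#' stratified fits are equivalent to a single regression with a
#' genotype-by-context interaction term.
#'
#' @param sample A [stratified_sample()] with both contexts polymorphic and
#'   at least two individuals each.
#' @return A list with elements `A` and `B`, each an `effect_estimate` with
#'   fields `slope`, `intercept`, `sampling_variance`, `residual_variance`,
#'   `se` and `n_used`.
#' @seealso [ols_additive()], [combination_weights()]
#' @export
ols_stratified <- function(sample) {
  assert_sample(sample)
  a <- sample$context == "A"
  list(
    A = ols_simple(sample$genotypes[a], sample$traits[a], "context A"),
    B = ols_simple(sample$genotypes[!a], sample$traits[!a], "context B")
  )
}

#' Pooled (additive) OLS fit
#'
#' Fits a single regression of trait on allele count over all individuals,
#' ignoring context. The resulting slope estimates both context-specific
#' effects; it is biased for either whenever they differ, but has lower
#' sampling variance than the stratified slopes.
#'
#' @param sample A [stratified_sample()] with polymorphic pooled genotypes.
#' @return An `effect_estimate` over all `n + m` individuals.
#' @export
ols_additive <- function(sample) {
  assert_sample(sample)
  ols_simple(sample$genotypes, sample$traits, "the pooled sample")
}

#' Weights expressing the pooled slope as a combination of stratified slopes
#'
#' For a within-context-centered sample, the pooled OLS slope equals
#' `omega_a * slope_A + omega_b * slope_B` with
#' `omega_a = sum_A (g - mean(g_A))^2 / sum_all (g - mean(g_all))^2` and
#' `omega_b` defined analogously. The numerators are `n` (resp. `m`) times
#' the sample heterozygosity, defined here as the genotypic variance
#' `sum((g - mean(g))^2) / count`, so `omega_a / omega_b = (n H_A) / (m H_B)`.
#' The weights are non-negative but need not sum to one; they do exactly when
#' the per-context genotype means coincide.
#'
#' @param sample A [stratified_sample()] with polymorphic pooled genotypes.
#' @return An object of class `"pooled_weights"`: list with `omega_a`,
#'   `omega_b`, `het_a`, `het_b`, `freq_a`, `freq_b`.
#' @export
combination_weights <- function(sample) {
  assert_sample(sample)
  a <- sample$context == "A"
  ga <- sample$genotypes[a]
  gb <- sample$genotypes[!a]
  g <- sample$genotypes
  sxx_all <- sum((g - mean(g))^2)
  if (sxx_all == 0) {
    gxe_stop("monomorphic genotypes in the pooled sample", "gxe_monomorphic")
  }
  sxx_a <- sum((ga - mean(ga))^2)
  sxx_b <- sum((gb - mean(gb))^2)
  structure(
    list(omega_a = sxx_a / sxx_all, omega_b = sxx_b / sxx_all,
         het_a = sxx_a / length(ga), het_b = sxx_b / length(gb),
         freq_a = mean(ga) / 2, freq_b = mean(gb) / 2),
    class = "pooled_weights"
  )
}

#' @export
print.pooled_weights <- function(x, ...) {
  cat(sprintf("pooled_weights: omega_a %.4f, omega_b %.4f (sum %.4f)\n",
              x$omega_a, x$omega_b, x$omega_a + x$omega_b))
  invisible(x)
}
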