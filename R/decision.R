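# The MSE decision rule: when is the pooled (additive) estimator more
# accurate than the stratified (GxE) estimator for a focal context?

#' Parameters of the additive-vs-GxE decision rule
#'
#' Bundles the quantities the rule needs for a focal context `A`: the two
#' context-specific effects (true values or plug-ins), the sampling variances
#' of the stratified estimators, and the combination weights of the pooled
#' estimator. The derived `noise_ratio` is `r = var_a / var_b`, the ratio of
#' focal to non-focal estimation noise.
#'
#' @param beta_a,beta_b Context-specific allelic effects (trait units per
#'   allele).
#' @param var_a,var_b Sampling variances of the stratified estimators
#'   (`V_A`, `V_B`); must be positive.
#' @param omega_a,omega_b Non-negative combination weights of the pooled
#'   estimator (see [combination_weights()]). `omega_b` defaults to
#'   `1 - omega_a`, the equal-heterozygosity case.
#' @return An object of class `"decision_input"`.
#' @export
decision_input <- function(beta_a, beta_b, var_a, var_b,
                           omega_a, omega_b = 1 - omega_a) {
  for (v in list(beta_a, beta_b, var_a, var_b, omega_a, omega_b)) {
    if (!is_number(v)) gxe_stop("all decision inputs must be single finite numbers")
  }
  if (var_a <= 0 || var_b <= 0) {
    gxe_stop("sampling variances must be positive", "gxe_nonpositive_variance")
  }
  if (omega_a < 0 || omega_b < 0) {
    gxe_stop("combination weights must be non-negative")
  }
  structure(
    list(beta_a = beta_a, beta_b = beta_b, var_a = var_a, var_b = var_b,
         omega_a = omega_a, omega_b = omega_b, noise_ratio = var_a / var_b),
    class = "decision_input"
  )
}

#' Mean-squared-error comparison of the additive and GxE estimators
#'
#' Computes, for the focal context, the MSE of the stratified estimator
#' (`var_a`: it is unbiased) and of the pooled estimator
#' (`((omega_a - 1) * beta_a + omega_b * beta_b)^2 +
#'   omega_a^2 * var_a + omega_b^2 * var_b`,
#' the squared bias plus the variance of the weighted combination). The GxE
#' estimator is preferred when its MSE is strictly smaller; ties resolve to
#' the additive estimator on parsimony grounds.
#'
#' @param input A [decision_input()].
#' @return An object of class `"gxe_decision"`: list with `mse_additive`,
#'   `mse_gxe`, `margin` (`mse_additive - mse_gxe`) and `preferred`
#'   (`"gxe"` iff `margin > 0`, else `"additive"`).
#' @examples
#' mse_pair(decision_input(0.1, 0.3, 0.005, 0.005, 0.5))
#' @export
mse_pair <- function(input) {
  if (!inherits(input, "decision_input")) {
    gxe_stop("expected a decision_input object")
  }
  bias <- (input$omega_a - 1) * input$beta_a + input$omega_b * input$beta_b
  mse_additive <- bias^2 +
    input$omega_a^2 * input$var_a + input$omega_b^2 * input$var_b
  mse_gxe <- input$var_a
  margin <- mse_additive - mse_gxe
  structure(
    list(mse_additive = mse_additive, mse_gxe = mse_gxe, margin = margin,
         preferred = if (margin > 0) "gxe" else "additive"),
    class = "gxe_decision"
  )
}

#' @export
print.gxe_decision <- function(x, ...) {
  cat(sprintf("decision: prefer %s (MSE additive %.6g, MSE GxE %.6g)\n",
              x$preferred, x$mse_additive, x$mse_gxe))
  invisible(x)
}

#' Signal-to-noise threshold of the decision rule (equal heterozygosity)
#'
#' Under equal per-context heterozygosity (`omega_a + omega_b = 1`) the rule
#' has a dimensionless form: the GxE estimator is preferred for the focal
#' context exactly when the signal-to-noise ratio
#' `(beta_a - beta_b)^2 / var_a` exceeds
#' `(1 + omega_a) / (1 - omega_a) - var_b / var_a`.
#' A negative threshold means the GxE estimator is preferred for every
#' signal, however small.
#'
#' @param omega_a Focal-context combination weight, strictly inside (0, 1).
#' @param var_ratio_ba The noise ratio `V_B / V_A` (non-focal over focal).
#' @return The threshold value (vectorised over its arguments).
#' @seealso [critical_noise_ratio()]
#' @export
snr_threshold <- function(omega_a, var_ratio_ba) {
  if (any(!is.finite(omega_a)) || any(omega_a <= 0) || any(omega_a >= 1)) {
    gxe_stop("omega_a must lie strictly inside (0, 1)")
  }
  if (any(!is.finite(var_ratio_ba)) || any(var_ratio_ba <= 0)) {
    gxe_stop("var_ratio_ba must be positive")
  }
  (1 + omega_a) / (1 - omega_a) - var_ratio_ba
}

#' Noise ratio below which the additive estimator is never preferable
#'
#' With equal heterozygosity, when the focal-to-non-focal noise ratio
#' `r = V_A / V_B` falls below `r* = (1 - omega_a) / (1 + omega_a)`, the
#' threshold of [snr_threshold()] is negative and the GxE estimator is
#' preferred for the focal context at any signal (for `omega_a = 1/2`,
#' `r* = 1/3`).
#'
#' @param omega_a Focal-context combination weight, strictly inside (0, 1).
#' @return The critical ratio `r*` (vectorised).
#' @export
critical_noise_ratio <- function(omega_a) {
  if (any(!is.finite(omega_a)) || any(omega_a <= 0) || any(omega_a >= 1)) {
    gxe_stop("omega_a must lie strictly inside (0, 1)")
  }
  (1 - omega_a) / (1 + omega_a)
}

#' Decision boundary under equal heterozygosity and equal noise
#'
#' In the special case `H_A = H_B` and `V_A = V_B` (so `omega_a = n/(n+m)`),
#' the two estimators have equal MSE for the focal context when
#' `V_A = (m / (2 n)) * delta_beta^2`. The boundary is returned on the
#' variance scale; take its square root for the standard-deviation scale
#' used in boundary plots.
#'
#' @param n,m Per-context sample counts (focal context has `n`).
#' @param delta_beta Difference in context-specific effects
#'   `beta_a - beta_b`.
#' @return `V_A` at the boundary; `0` when `delta_beta = 0` (the additive
#'   estimator is then weakly preferred everywhere).
#' @export
boundary_equal_het <- function(n, m, delta_beta) {
  if (any(n < 1) || any(m < 1)) gxe_stop("n and m must be at least 1")
  (m / (2 * n)) * delta_beta^2
}
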