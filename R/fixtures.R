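# Synthetic-data generators standing in for external inputs: sex-stratified
# GWAS summary statistics (for the genome-wide screen) and paired
# standard-error tables (for the gene-by-diet simulator). Both return the
# generating truth so downstream estimates can be scored against it.

#' Configuration of the synthetic summary-statistic generator
#'
#' Emulates two-context GWAS summary statistics in the regime where each
#' variant explains little trait variance: the sampling variance of a
#' context's effect estimate is `trait_var / (n_context * 2 f (1 - f))`,
#' i.e. a matter of trait variance and heterozygosity alone. True effects
#' come from the same null/equal/amplified mixture as the polygenic-score
#' simulations, scaled by `effect_sd`.
#'
#' @param n_variants Number of variants; default 10000.
#' @param n_blocks Number of contiguous LD blocks; default 1700.
#' @param null_fraction,equal_share,amp_factor Mixture parameters as in
#'   [pgs_sim_config()].
#' @param effect_sd Standard-deviation scale applied to the unit-variance
#'   effect mixture; default 0.02 trait units per allele.
#' @param n,m Per-context GWAS sample sizes; defaults 150000 each.
#' @param trait_var_a,trait_var_b Per-context trait variances; defaults 1.
#' @param maf_shape1,maf_shape2 Allele-frequency Beta parameters.
#' @param seed Optional RNG seed.
#' @return An object of class `"summary_stat_config"`.
#' @export
summary_stat_config <- function(n_variants = 10000, n_blocks = 1700,
                                null_fraction = 0.5, equal_share = 0.5,
                                amp_factor = 1.5, effect_sd = 0.02,
                                n = 150000, m = 150000,
                                trait_var_a = 1, trait_var_b = 1,
                                maf_shape1 = 1, maf_shape2 = 5, seed = NULL) {
  if (n_variants < 1 || n_blocks < 1) gxe_stop("sizes must be positive")
  if (n < 1 || m < 1) gxe_stop("sample sizes must be positive")
  if (trait_var_a <= 0 || trait_var_b <= 0) {
    gxe_stop("trait variances must be positive")
  }
  if (effect_sd < 0) gxe_stop("effect_sd must be non-negative")
  structure(
    list(n_variants = as.integer(n_variants), n_blocks = as.integer(n_blocks),
         null_fraction = null_fraction, equal_share = equal_share,
         amp_factor = amp_factor, effect_sd = effect_sd,
         n = n, m = m, trait_var_a = trait_var_a, trait_var_b = trait_var_b,
         maf_shape1 = maf_shape1, maf_shape2 = maf_shape2, seed = seed),
    class = "summary_stat_config"
  )
}

#' Generate synthetic two-context GWAS summary statistics
#'
#' Draws true effects and allele frequencies, sets per-context sampling
#' variances `V = trait_var / (n * 2 f (1 - f))`, perturbs the truth with
#' Gaussian noise of that variance, and assigns contiguous block ids.
#'
#' @param config A [summary_stat_config()].
#' @return A list with `records` (a summary-statistic `data.frame` as read
#'   by [read_summary_table()], including `pval_a` and `block_id`) and
#'   `truth` (`variant_id`, true `beta_a`, `beta_b`, `freq`, `component`).
#' @export
generate_summary_stats <- function(config) {
  stopifnot(inherits(config, "summary_stat_config"))
  maybe_seed(config$seed)
  p <- config$n_variants
  u <- stats::runif(p)
  component <- ifelse(u < config$null_fraction, "null",
                      ifelse(u < config$null_fraction +
                               (1 - config$null_fraction) * config$equal_share,
                             "equal", "amplified"))
  a <- config$amp_factor
  effects <- matrix(0, p, 2)
  eq <- component == "equal"
  am <- component == "amplified"
  if (any(eq)) effects[eq, ] <- rmvn_psd(sum(eq), c(0, 0), matrix(1, 2, 2))
  if (any(am)) {
    effects[am, ] <- rmvn_psd(sum(am), c(0, 0),
                              matrix(c(a, 1, 1, 1 / a), 2))
  }
  effects <- effects * config$effect_sd
  freq <- 0.5 * stats::rbeta(p, config$maf_shape1, config$maf_shape2)
  het <- 2 * freq * (1 - freq)
  v_a <- config$trait_var_a / (config$n * het)
  v_b <- config$trait_var_b / (config$m * het)
  beta_a_hat <- stats::rnorm(p, effects[, 1], sqrt(v_a))
  beta_b_hat <- stats::rnorm(p, effects[, 2], sqrt(v_b))
  ids <- sprintf("v%06d", seq_len(p))
  records <- data.frame(
    variant_id = ids,
    beta_a = beta_a_hat, se_a = sqrt(v_a),
    beta_b = beta_b_hat, se_b = sqrt(v_b),
    pval_a = pmax(2 * stats::pnorm(-abs(beta_a_hat) / sqrt(v_a)), 1e-300),
    block_id = as.integer(cut(seq_len(p), breaks = config$n_blocks)),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(variant_id = ids, beta_a = effects[, 1],
                      beta_b = effects[, 2], freq = freq,
                      component = component, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Configuration of the paired standard-error surrogate
#'
#' A parametric stand-in for an empirical per-variant SE table: paired
#' log-normal draws with configurable between-diet correlation on the log
#' scale. The default location and scale give SE magnitudes of roughly
#' 0.05-0.3, the scale of per-variant survival-proxy effect estimates in
#' caged-fly association data; the values are otherwise arbitrary.
#'
#' @param meanlog_control,meanlog_sugar Log-scale locations; defaults
#'   `log(0.12)`.
#' @param sdlog_control,sdlog_sugar Log-scale spreads; defaults 0.4.
#' @param corr Between-diet correlation of the log SEs; default 0.8.
#' @param n_records Number of donor records; default 10000.
#' @param seed Optional RNG seed.
#' @return An object of class `"se_surrogate_config"`.
#' @export
se_surrogate_config <- function(meanlog_control = log(0.12),
                                meanlog_sugar = log(0.12),
                                sdlog_control = 0.4, sdlog_sugar = 0.4,
                                corr = 0.8, n_records = 10000, seed = NULL) {
  if (sdlog_control < 0 || sdlog_sugar < 0) gxe_stop("sdlog must be non-negative")
  if (abs(corr) > 1) gxe_stop("corr must lie in [-1, 1]")
  if (n_records < 1) gxe_stop("n_records must be positive")
  structure(
    list(meanlog_control = meanlog_control, meanlog_sugar = meanlog_sugar,
         sdlog_control = sdlog_control, sdlog_sugar = sdlog_sugar,
         corr = corr, n_records = as.integer(n_records), seed = seed),
    class = "se_surrogate_config"
  )
}

#' Generate a paired log-normal standard-error table
#'
#' @param config A [se_surrogate_config()].
#' @return A `data.frame` with positive columns `s_control` and `s_sugar`,
#'   suitable as the `se_resource` of [simulate_estimates()].
#' @export
generate_se_surrogate <- function(config = se_surrogate_config()) {
  stopifnot(inherits(config, "se_surrogate_config"))
  maybe_seed(config$seed)
  cov <- matrix(c(config$sdlog_control^2,
                  config$corr * config$sdlog_control * config$sdlog_sugar,
                  config$corr * config$sdlog_control * config$sdlog_sugar,
                  config$sdlog_sugar^2), 2)
  logs <- rmvn_psd(config$n_records,
                   c(config$meanlog_control, config$meanlog_sugar), cov)
  data.frame(s_control = exp(logs[, 1]), s_sugar = exp(logs[, 2]))
}
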