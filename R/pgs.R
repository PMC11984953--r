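# Polygenic-score simulation under partial amplification: generate
# two-context GWAS training data, build scores under four
# ascertainment/estimation strategies, and evaluate out-of-sample
# correlation with the trait.

#' Configuration of the polygenic-score simulation
#'
#' True effects follow the mixture
#' `pi0 * delta_0 + (1 - pi0) * (alpha * N(0, equal_cov) +
#'  (1 - alpha) * N(0, amp_cov))`
#' with `equal_cov = [[1, 1], [1, 1]]` (identical effects in both contexts)
#' and `amp_cov = [[a, 1], [1, 1/a]]` (perfectly correlated effects with
#' context-A standard deviation `a` times context-B's; default `a = 1.5`).
#' Minor allele frequencies are `0.5 * Beta(s1, s2)`; genotypes are
#' `Binomial(2, f)`; the environmental variance in each context is set from
#' that context's expected genetic variance so the narrow-sense heritability
#' equals `h2`.
#'
#' @param n_variants Number of variants `p`; default 5000.
#' @param null_fraction Proportion with null effects in both contexts
#'   (`pi0`); default 0.5.
#' @param equal_share Proportion `alpha` of non-null variants with exactly
#'   equal effects; default 0.5.
#' @param amp_factor Amplification sd ratio `a`; default 1.5.
#' @param maf_shape1,maf_shape2 Beta parameters of the allele-frequency
#'   distribution; defaults 1 and 5.
#' @param h2 Narrow-sense heritability per context; default 0.4.
#' @param n_train,n_test Per-context training and test sample sizes;
#'   defaults 1000 and 3000.
#' @param n_ascertain Number of score variants; default one-third of the
#'   expected causal count (833 at the defaults).
#' @param n_reps Replicates for [run_experiment()]; default 200.
#' @param seed Optional base RNG seed.
#' @return An object of class `"pgs_sim_config"`.
#' @export
pgs_sim_config <- function(n_variants = 5000, null_fraction = 0.5,
                           equal_share = 0.5, amp_factor = 1.5,
                           maf_shape1 = 1, maf_shape2 = 5, h2 = 0.4,
                           n_train = 1000, n_test = 3000,
                           n_ascertain = NULL, n_reps = 200, seed = NULL) {
  if (!is_number(null_fraction) || null_fraction < 0 || null_fraction > 1) {
    gxe_stop("null_fraction must lie in [0, 1]")
  }
  if (!is_number(equal_share) || equal_share < 0 || equal_share > 1) {
    gxe_stop("equal_share must lie in [0, 1]")
  }
  if (!is_number(h2) || h2 <= 0 || h2 >= 1) gxe_stop("h2 must lie in (0, 1)")
  if (!is_number(amp_factor) || amp_factor <= 0) {
    gxe_stop("amp_factor must be positive")
  }
  equal_cov <- matrix(1, 2, 2)
  amp_cov <- matrix(c(amp_factor, 1, 1, 1 / amp_factor), 2)
  check_psd(equal_cov, "equal_cov")
  check_psd(amp_cov, "amp_cov")
  n_causal <- round(n_variants * (1 - null_fraction))
  if (is.null(n_ascertain)) n_ascertain <- max(1L, floor(n_causal / 3))
  if (n_ascertain < 1 || n_ascertain > n_variants) {
    gxe_stop("n_ascertain must lie in [1, n_variants]")
  }
  structure(
    list(n_variants = as.integer(n_variants), null_fraction = null_fraction,
         equal_share = equal_share, amp_factor = amp_factor,
         equal_cov = equal_cov, amp_cov = amp_cov,
         maf_shape1 = maf_shape1, maf_shape2 = maf_shape2, h2 = h2,
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         n_ascertain = as.integer(n_ascertain), n_reps = as.integer(n_reps),
         seed = seed),
    class = "pgs_sim_config"
  )
}

#' Draw a true genetic architecture
#'
#' Assigns each variant to the null, equal-effects or amplified component by
#' the configured probabilities, draws its effect pair from the component's
#' bivariate normal, and draws its allele frequency from
#' `0.5 * Beta(s1, s2)`.
#'
#' @param config A [pgs_sim_config()].
#' @return A list of class `"true_architecture"`: `effects` (p x 2 matrix,
#'   contexts A and B), `freqs`, `component` (factor with levels `null`,
#'   `equal`, `amplified`).
#' @export
draw_architecture <- function(config) {
  stopifnot(inherits(config, "pgs_sim_config"))
  p <- config$n_variants
  u <- stats::runif(p)
  component <- ifelse(u < config$null_fraction, "null",
                      ifelse(u < config$null_fraction +
                               (1 - config$null_fraction) * config$equal_share,
                             "equal", "amplified"))
  effects <- matrix(0, p, 2, dimnames = list(NULL, c("A", "B")))
  eq <- component == "equal"
  am <- component == "amplified"
  if (any(eq)) effects[eq, ] <- rmvn_psd(sum(eq), c(0, 0), config$equal_cov)
  if (any(am)) effects[am, ] <- rmvn_psd(sum(am), c(0, 0), config$amp_cov)
  freqs <- 0.5 * stats::rbeta(p, config$maf_shape1, config$maf_shape2)
  structure(
    list(effects = effects, freqs = freqs,
         component = factor(component, levels = c("null", "equal", "amplified"))),
    class = "true_architecture"
  )
}

# Expected genetic variance sum(2 f (1 - f) beta^2) and the environmental
# variance delivering heritability h2. A fully null architecture has zero
# genetic variance; unit environmental variance is used so traits remain
# well defined.
environmental_variance <- function(beta, freqs, h2) {
  var_g <- sum(2 * freqs * (1 - freqs) * beta^2)
  if (var_g == 0) 1 else var_g * (1 - h2) / h2
}

#' Simulate a genotyped cohort in one context
#'
#' Genotypes are independent `Binomial(2, f_j)` draws; traits are
#' `G beta + N(0, sigma2)` with `sigma2` set from the expected genetic
#' variance so the narrow-sense heritability equals `config$h2` (unit
#' environmental variance if the architecture is fully null).
#'
#' @param arch A [draw_architecture()] result.
#' @param config A [pgs_sim_config()].
#' @param context `"A"` or `"B"`.
#' @param n Number of individuals.
#' @return A list of class `"cohort"`: `G` (n x p), `y`, `genetic` (true
#'   genetic values), `sigma2`, `context`.
#' @export
simulate_cohort <- function(arch, config, context = "A", n = config$n_train) {
  stopifnot(inherits(arch, "true_architecture"))
  if (!context %in% c("A", "B")) gxe_stop("context must be A or B")
  if (n < 1) gxe_stop("n must be at least 1")
  p <- length(arch$freqs)
  beta <- arch$effects[, context]
  G <- matrix(stats::rbinom(n * p, 2L, rep(arch$freqs, each = n)), n, p)
  genetic <- drop(G %*% beta)
  sigma2 <- environmental_variance(beta, arch$freqs, config$h2)
  y <- genetic + stats::rnorm(n, 0, sqrt(sigma2))
  structure(list(G = G, y = y, genetic = genetic, sigma2 = sigma2,
                 context = context),
            class = "cohort")
}

#' Realized heritability of the trait generator
#'
#' Streams genotype generation in column blocks (so large cohorts never
#' materialise a full genotype matrix) and returns the realized
#' `Var(G beta) / Var(y)` in each context.
#'
#' @param arch A [draw_architecture()] result.
#' @param config A [pgs_sim_config()].
#' @param n Individuals per context.
#' @param block_size Variants generated per block; default 500.
#' @return Named numeric vector with elements `A` and `B`.
#' @export
realized_heritability <- function(arch, config, n, block_size = 500) {
  p <- length(arch$freqs)
  out <- c(A = NA_real_, B = NA_real_)
  for (context in c("A", "B")) {
    beta <- arch$effects[, context]
    genetic <- numeric(n)
    for (start in seq(1L, p, by = block_size)) {
      ix <- start:min(start + block_size - 1L, p)
      Gb <- matrix(stats::rbinom(n * length(ix), 2L,
                                 rep(arch$freqs[ix], each = n)),
                   n, length(ix))
      genetic <- genetic + drop(Gb %*% beta[ix])
    }
    sigma2 <- environmental_variance(beta, arch$freqs, config$h2)
    y <- genetic + stats::rnorm(n, 0, sqrt(sigma2))
    out[context] <- stats::var(genetic) / stats::var(y)
  }
  out
}

# Vectorised per-variant simple regression of y on each genotype column.
# Returns slope, se (normal-theory, residual df n - 2) and two-sided
# z-based p-value; monomorphic columns yield NA.
column_ols <- function(G, y) {
  n <- length(y)
  yc <- y - mean(y)
  gbar <- colMeans(G)
  sxx <- colSums(G^2) - n * gbar^2
  sxy <- drop(crossprod(G, yc))
  poly <- sxx > 0
  slope <- ifelse(poly, sxy / sxx, NA_real_)
  rss <- sum(yc^2) - ifelse(poly, slope^2 * sxx, 0)
  se <- ifelse(poly, sqrt(pmax(rss, 0) / (n - 2) / sxx), NA_real_)
  p <- ifelse(poly & se > 0, 2 * stats::pnorm(-abs(slope / se)), NA_real_)
  data.frame(beta = slope, se = se, p = p)
}

#' Per-variant GWAS in two contexts: stratified and pooled fits
#'
#' Because variants are generated independently, marginal (single-variant)
#' OLS is the correct per-variant model. The stratified fits regress each
#' context's trait on each genotype column; the additive fit pools the two
#' cohorts after centering traits within context (which makes the pooled
#' slope the omega-weighted combination of the stratified slopes).
#'
#' @param cohort_a,cohort_b [simulate_cohort()] results sharing a variant
#'   panel.
#' @return A `data.frame` with columns `beta_add`, `se_add`, `p_add`,
#'   `beta_a`, `se_a`, `p_a`, `beta_b`, `se_b`, `p_b`. Monomorphic variants
#'   are `NA`.
#' @export
marginal_gwas <- function(cohort_a, cohort_b) {
  stopifnot(inherits(cohort_a, "cohort"), inherits(cohort_b, "cohort"))
  if (ncol(cohort_a$G) != ncol(cohort_b$G)) {
    gxe_stop("cohorts must share the variant panel")
  }
  fa <- column_ols(cohort_a$G, cohort_a$y)
  fb <- column_ols(cohort_b$G, cohort_b$y)
  G_pool <- rbind(cohort_a$G, cohort_b$G)
  y_pool <- c(cohort_a$y - mean(cohort_a$y), cohort_b$y - mean(cohort_b$y))
  fp <- column_ols(G_pool, y_pool)
  data.frame(beta_add = fp$beta, se_add = fp$se, p_add = fp$p,
             beta_a = fa$beta, se_a = fa$se, p_a = fa$p,
             beta_b = fb$beta, se_b = fb$se, p_b = fb$p)
}

#' Ascertain the k most significant variants
#'
#' Indices of the `k` smallest finite values (p-values or pseudo p-values);
#' ties resolve to the lower index (for p-values computed from z-statistics
#' a p tie is a |z| tie).
#'
#' @param values Numeric vector; `NA`/non-finite entries are never selected.
#' @param k Number of variants to select.
#' @return Integer index vector of length `k`.
#' @export
ascertain <- function(values, k) {
  finite <- which(is.finite(values))
  if (k > length(finite)) {
    gxe_stop(sprintf("k = %d exceeds the %d finite entries", k,
                     length(finite)), "gxe_too_large")
  }
  finite[order(values[finite])[seq_len(k)]]
}

score_correlation <- function(G, w, ix, y) {
  wv <- w[ix]
  wv[!is.finite(wv)] <- 0  # unusable weights contribute nothing
  score <- drop(G[, ix, drop = FALSE] %*% wv)
  if (stats::sd(score) == 0 || stats::sd(y) == 0) {
    warning("constant polygenic score: correlation recorded as 0")
    return(0)
  }
  stats::cor(score, y)
}

PGS_METHODS <- c("additive", "additive_gxe", "gxe", "mash")

#' Build and evaluate the four polygenic-score strategies
#'
#' Strategies (ascertainment + estimation):
#' \describe{
#'   \item{`additive`}{pooled p-values; pooled (additive) weights, shared by
#'     both contexts.}
#'   \item{`additive_gxe`}{pooled p-values (low-variance ascertainment);
#'     per-context stratified weights (low-bias estimation).}
#'   \item{`gxe`}{per-context p-values and per-context stratified weights,
#'     with each context's variant set selected independently.}
#'   \item{`mash`}{empirical-Bayes shrinkage ([mash_lite()]) of the
#'     stratified panel; per-context pseudo p-values for ascertainment and
#'     posterior means as weights.}
#' }
#' When `shrinkage = TRUE` (default), the additive and stratified weights
#' are first shrunk with the univariate empirical-Bayes mixture
#' ([shrink_univariate()]); ascertainment always uses the raw p-values.
#'
#' @param gwas A [marginal_gwas()] table from the training cohorts.
#' @param test_a,test_b Test cohorts from [simulate_cohort()].
#' @param config A [pgs_sim_config()] (supplies `n_ascertain`).
#' @param shrinkage Apply univariate EB shrinkage to the additive/GxE
#'   weights; default `TRUE`.
#' @return A `data.frame` with columns `method`, `context`, `correlation`.
#' @export
build_and_evaluate_scores <- function(gwas, test_a, test_b, config,
                                      shrinkage = TRUE) {
  k <- config$n_ascertain
  ok <- is.finite(gwas$beta_a) & is.finite(gwas$beta_b) &
    is.finite(gwas$beta_add)
  w_add <- gwas$beta_add
  w_a <- gwas$beta_a
  w_b <- gwas$beta_b
  if (shrinkage) {
    w_add[ok] <- shrink_univariate(gwas$beta_add[ok], gwas$se_add[ok])$posterior_mean
    w_a[ok] <- shrink_univariate(gwas$beta_a[ok], gwas$se_a[ok])$posterior_mean
    w_b[ok] <- shrink_univariate(gwas$beta_b[ok], gwas$se_b[ok])$posterior_mean
  }
  ml <- mash_lite(cbind(gwas$beta_a[ok], gwas$beta_b[ok]),
                  cbind(gwas$se_a[ok], gwas$se_b[ok]))
  pm_a <- pm_b <- rep(NA_real_, nrow(gwas))
  pp_a <- pp_b <- rep(NA_real_, nrow(gwas))
  pm_a[ok] <- ml$posterior_means[, 1]
  pm_b[ok] <- ml$posterior_means[, 2]
  pp <- pseudo_pvalues(ml$posterior_means, ml$posterior_sds)
  pp_a[ok] <- pp[, 1]
  pp_b[ok] <- pp[, 2]

  ix_add <- ascertain(gwas$p_add, k)
  ix_a <- ascertain(gwas$p_a, k)
  ix_b <- ascertain(gwas$p_b, k)
  ix_ma <- ascertain(pp_a, k)
  ix_mb <- ascertain(pp_b, k)

  rows <- list(
    list("additive", "A", score_correlation(test_a$G, w_add, ix_add, test_a$y)),
    list("additive", "B", score_correlation(test_b$G, w_add, ix_add, test_b$y)),
    list("additive_gxe", "A", score_correlation(test_a$G, w_a, ix_add, test_a$y)),
    list("additive_gxe", "B", score_correlation(test_b$G, w_b, ix_add, test_b$y)),
    list("gxe", "A", score_correlation(test_a$G, w_a, ix_a, test_a$y)),
    list("gxe", "B", score_correlation(test_b$G, w_b, ix_b, test_b$y)),
    list("mash", "A", score_correlation(test_a$G, pm_a, ix_ma, test_a$y)),
    list("mash", "B", score_correlation(test_b$G, pm_b, ix_mb, test_b$y))
  )
  data.frame(method = vapply(rows, `[[`, character(1), 1L),
             context = vapply(rows, `[[`, character(1), 2L),
             correlation = vapply(rows, `[[`, numeric(1), 3L),
             stringsAsFactors = FALSE)
}

#' One full replicate of the polygenic-score experiment
#'
#' Draws an architecture, simulates training and test cohorts in both
#' contexts, runs the training GWAS, and evaluates all four strategies.
#'
#' @param config A [pgs_sim_config()].
#' @param shrinkage Passed to [build_and_evaluate_scores()].
#' @return The score `data.frame` of [build_and_evaluate_scores()].
#' @export
run_pgs_rep <- function(config, shrinkage = TRUE) {
  arch <- draw_architecture(config)
  train_a <- simulate_cohort(arch, config, "A", config$n_train)
  train_b <- simulate_cohort(arch, config, "B", config$n_train)
  gwas <- marginal_gwas(train_a, train_b)
  test_a <- simulate_cohort(arch, config, "A", config$n_test)
  test_b <- simulate_cohort(arch, config, "B", config$n_test)
  build_and_evaluate_scores(gwas, test_a, test_b, config, shrinkage)
}

#' Run the polygenic-score experiment over a parameter grid
#'
#' Loops over the grid of `alpha` (share of non-null variants with equal
#' effects) and training sample size, running `config$n_reps` seeded
#' replicates per cell. Each replicate uses its own RNG stream derived from
#' the base seed by a running counter, so partial reruns reproduce the full
#' run.
#'
#' @param config A [pgs_sim_config()]; its `equal_share` and `n_train` are
#'   overridden by the grid.
#' @param alphas Grid of equal-effect shares; default
#'   `c(0, 0.25, 0.5, 0.75, 1)`.
#' @param n_trains Grid of training sizes; default `c(1000, 50000)`.
#' @param shrinkage Passed to [build_and_evaluate_scores()].
#' @return A list with `results` (tidy per-replicate table: `alpha`,
#'   `n_train`, `method`, `context`, `rep`, `correlation`) and `summary`
#'   (per-cell mean correlation and Monte-Carlo standard error).
#' @export
run_experiment <- function(config, alphas = c(0, 0.25, 0.5, 0.75, 1),
                           n_trains = c(1000, 50000), shrinkage = TRUE) {
  base_seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  counter <- 0L
  out <- list()
  for (n_train in n_trains) {
    for (alpha in alphas) {
      cell_cfg <- config
      cell_cfg$equal_share <- alpha
      cell_cfg$n_train <- as.integer(n_train)
      for (r in seq_len(config$n_reps)) {
        counter <- counter + 1L
        set.seed((base_seed + counter) %% .Machine$integer.max)
        sc <- run_pgs_rep(cell_cfg, shrinkage)
        sc$alpha <- alpha
        sc$n_train <- n_train
        sc$rep <- r
        out[[length(out) + 1L]] <- sc
      }
    }
  }
  results <- do.call(rbind, out)
  agg <- stats::aggregate(correlation ~ alpha + n_train + method + context,
                          data = results, FUN = mean)
  names(agg)[names(agg) == "correlation"] <- "mean_correlation"
  agg$se <- stats::aggregate(correlation ~ alpha + n_train + method + context,
                             data = results,
                             FUN = function(x) stats::sd(x) / sqrt(length(x)))$correlation
  list(results = results, summary = agg)
}
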