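# Genome-wide application of the decision rule to two-context GWAS summary
# statistics: per-variant verdicts, block-resampled preferred-GxE fractions,
# and data-splitting validation of the predicted MSE difference.

#' Configuration of the genome-wide decision-rule screen
#'
#' @param focal_context Context whose effects are being estimated, `"A"` or
#'   `"B"`. Verdicts always concern the focal context.
#' @param noise_ratio_proxy Assumed noise ratio `r = V_focal / V_other`,
#'   constant across variants. When per-variant effects explain little trait
#'   variance and heterozygosity is shared across contexts (autosomal
#'   variants in the two sexes, for example), `r` is well approximated by the
#'   ratio of context-specific trait variances.
#' @param omega_focal Combination weight of the focal context, default 1/2
#'   (equal per-context sample sizes and heterozygosities). Must be in (0, 1).
#' @param sig_threshold Focal-context p-value cutoff used when restricting to
#'   genome-wide significant variants; default `5e-8`.
#' @param n_block_draws Number of one-variant-per-block resampling
#'   repetitions in [fraction_gxe_preferred()]; default 10.
#' @param seed Optional RNG seed for the block resampling.
#' @return An object of class `"screen_config"`.
#' @export
screen_config <- function(focal_context = "A", noise_ratio_proxy = 1,
                          omega_focal = 0.5, sig_threshold = 5e-8,
                          n_block_draws = 10, seed = NULL) {
  if (!focal_context %in% c("A", "B")) gxe_stop("focal_context must be A or B")
  if (!is_number(noise_ratio_proxy) || noise_ratio_proxy <= 0) {
    gxe_stop("noise_ratio_proxy must be a positive number")
  }
  if (!is_number(omega_focal) || omega_focal <= 0 || omega_focal >= 1) {
    gxe_stop("omega_focal must lie strictly inside (0, 1)")
  }
  if (!is_number(sig_threshold) || sig_threshold <= 0 || sig_threshold >= 1) {
    gxe_stop("sig_threshold must lie in (0, 1)")
  }
  structure(
    list(focal_context = focal_context, noise_ratio_proxy = noise_ratio_proxy,
         omega_focal = omega_focal, sig_threshold = sig_threshold,
         n_block_draws = as.integer(n_block_draws), seed = seed),
    class = "screen_config"
  )
}

# Reorient records so that columns *_a refer to the focal context.
orient_focal <- function(records, config) {
  if (config$focal_context == "B") {
    records[c("beta_a", "beta_b")] <- records[c("beta_b", "beta_a")]
    records[c("se_a", "se_b")] <- records[c("se_b", "se_a")]
  }
  records
}

#' Per-variant additive-vs-GxE verdicts from summary statistics
#'
#' Applies the dimensionless decision rule to each record, with plug-in
#' signal `(beta_focal - beta_other)^2 / se_focal^2` compared against
#' [snr_threshold()] evaluated at `omega_focal` and
#' `V_other / V_focal = 1 / noise_ratio_proxy`. The verdict does not depend
#' on the significance threshold; `significant_only` merely restricts which
#' records are returned.
#'
#' @param records Summary-statistic `data.frame`
#'   (see [read_summary_table()]).
#' @param config A [screen_config()].
#' @param significant_only If `TRUE`, keep only records with focal-context
#'   p-value below `config$sig_threshold` (requires a `pval_a` column and
#'   focal context `"A"`).
#' @param noise_corrected If `TRUE`, subtract the estimation-noise
#'   contribution `se_focal^2 * (1 + 1/r)` from the squared effect
#'   difference before forming the signal-to-noise ratio. The naive plug-in
#'   squared difference is inflated by estimation noise; the corrected form
#'   estimates the expected MSE ranking, while the plug-in form matches
#'   boundary plots of observed `|beta_a - beta_b|` against `se_a`.
#' @return The records with added columns `snr`, `snr_cutoff` and
#'   `preferred` (`"additive"` or `"gxe"`). Records with missing or
#'   non-finite standard errors are dropped with a warning.
#' @export
classify_loci <- function(records, config, significant_only = FALSE,
                          noise_corrected = FALSE) {
  validate_summary_records(records)
  if (!inherits(config, "screen_config")) gxe_stop("expected a screen_config")
  oriented <- orient_focal(records, config)
  ok <- is.finite(oriented$se_a) & is.finite(oriented$beta_a) &
    is.finite(oriented$beta_b)
  if (!all(ok)) {
    warning(sprintf("dropping %d record(s) with missing effects or SEs",
                    sum(!ok)))
    records <- records[ok, , drop = FALSE]
    oriented <- oriented[ok, , drop = FALSE]
  }
  if (significant_only) {
    if (!"pval_a" %in% names(records)) {
      gxe_stop("significant_only requires a pval_a column", "gxe_bad_table")
    }
    keep <- !is.na(records$pval_a) & records$pval_a < config$sig_threshold
    records <- records[keep, , drop = FALSE]
    oriented <- oriented[keep, , drop = FALSE]
  }
  diff2 <- (oriented$beta_a - oriented$beta_b)^2
  if (noise_corrected) {
    diff2 <- diff2 - oriented$se_a^2 * (1 + 1 / config$noise_ratio_proxy)
  }
  snr <- diff2 / oriented$se_a^2
  cutoff <- snr_threshold(config$omega_focal, 1 / config$noise_ratio_proxy)
  records$snr <- snr
  records$snr_cutoff <- cutoff
  records$preferred <- ifelse(snr > cutoff, "gxe", "additive")
  records
}

#' Block-resampled fraction of variants better estimated under GxE
#'
#' Repeatedly samples one variant per LD block uniformly at random (so that
#' approximately independent variants enter each draw), computes the percent
#' of sampled variants whose verdict is `"gxe"`, and averages over draws.
#' By default the verdicts use the noise-corrected signal (see
#' [classify_loci()]): the quantity reported is the expected percent of
#' effects better estimated under GxE, which the naive plug-in signal
#' overstates for near-null variants.
#'
#' @param records Summary-statistic `data.frame` with a `block_id` column.
#' @param config A [screen_config()]; `n_block_draws` and `seed` control the
#'   resampling.
#' @param significant_only Passed to [classify_loci()].
#' @param noise_corrected Passed to [classify_loci()]; default `TRUE` here.
#' @return A list with `percent` (mean over draws), `per_draw` (percent in
#'   each draw) and `n_blocks`.
#' @export
fraction_gxe_preferred <- function(records, config, significant_only = FALSE,
                                   noise_corrected = TRUE) {
  classified <- classify_loci(records, config,
                              significant_only = significant_only,
                              noise_corrected = noise_corrected)
  if (!"block_id" %in% names(classified) || all(is.na(classified$block_id))) {
    gxe_stop("block resampling requires a block_id column",
             "gxe_missing_blocks")
  }
  classified <- classified[!is.na(classified$block_id), , drop = FALSE]
  if (nrow(classified) == 0L) {
    gxe_stop("no records with block ids", "gxe_missing_blocks")
  }
  maybe_seed(config$seed)
  by_block <- split(seq_len(nrow(classified)), classified$block_id)
  per_draw <- vapply(seq_len(config$n_block_draws), function(d) {
    picked <- vapply(by_block, function(ix) {
      if (length(ix) == 1L) ix else sample(ix, 1L)
    }, integer(1))
    100 * mean(classified$preferred[picked] == "gxe")
  }, numeric(1))
  list(percent = mean(per_draw), per_draw = per_draw,
       n_blocks = length(by_block))
}

#' Data-splitting validation of the predicted MSE difference
#'
#' For each variant, predicts the additive-minus-GxE MSE difference from the
#' training split using the noise-corrected signal
#' `(beta_a - beta_b)^2 - se_a^2 - se_b^2` (the naive squared difference is
#' inflated by estimation noise) inside the bias-variance decomposition, and
#' evaluates it against the holdout split via
#' `(beta_additive_train - beta_focal_holdout)^2 -
#'  (beta_focal_train - beta_focal_holdout)^2`,
#' whose expectation equals the true MSE difference because the holdout noise
#' cancels in the difference. The training additive estimate is the
#' omega-weighted combination of the training stratified estimates.
#'
#' @param train,holdout Summary-statistic `data.frame`s over the same
#'   variants (matched by `variant_id`).
#' @param config A [screen_config()]; `omega_focal` supplies the weights.
#' @param n_bins Number of quantile bins for the calibration summary.
#' @return A list with `variants` (per-variant `predicted_diff` and
#'   `realized_diff`) and `calibration` (per-bin means of both, the
#'   Monte-Carlo standard error of the realized mean, and `se_diff`, the
#'   standard error of the realized-minus-predicted difference — the
#'   relevant yardstick for calibration, since true-margin variation within
#'   a bin is shared by the two quantities and cancels).
#' @export
split_validate <- function(train, holdout, config, n_bins = 10) {
  validate_summary_records(train)
  validate_summary_records(holdout)
  if (!inherits(config, "screen_config")) gxe_stop("expected a screen_config")
  unmatched <- c(setdiff(train$variant_id, holdout$variant_id),
                 setdiff(holdout$variant_id, train$variant_id))
  if (length(unmatched)) {
    gxe_stop(sprintf("unmatched variant ids across splits: %s%s",
                     paste(utils::head(unmatched, 5), collapse = ", "),
                     if (length(unmatched) > 5) ", ..." else ""),
             "gxe_unmatched_ids")
  }
  holdout <- holdout[match(train$variant_id, holdout$variant_id), , drop = FALSE]
  tr <- orient_focal(train, config)
  ho <- orient_focal(holdout, config)

  w_a <- config$omega_focal
  w_b <- 1 - w_a
  v_a <- tr$se_a^2
  v_b <- tr$se_b^2
  signal2 <- (tr$beta_a - tr$beta_b)^2 - v_a - v_b
  predicted <- w_b^2 * signal2 + w_a^2 * v_a + w_b^2 * v_b - v_a

  beta_add_train <- w_a * tr$beta_a + w_b * tr$beta_b
  realized <- (beta_add_train - ho$beta_a)^2 - (tr$beta_a - ho$beta_a)^2

  variants <- data.frame(variant_id = train$variant_id,
                         predicted_diff = predicted,
                         realized_diff = realized,
                         stringsAsFactors = FALSE)
  qs <- stats::quantile(predicted, probs = seq(0, 1, length.out = n_bins + 1))
  bins <- cut(predicted, breaks = unique(qs), include.lowest = TRUE)
  calibration <- do.call(rbind, lapply(split(variants, bins), function(d) {
    delta <- d$realized_diff - d$predicted_diff
    data.frame(n = nrow(d),
               mean_predicted = mean(d$predicted_diff),
               mean_realized = mean(d$realized_diff),
               se_realized = stats::sd(d$realized_diff) / sqrt(nrow(d)),
               se_diff = stats::sd(delta) / sqrt(nrow(d)))
  }))
  calibration$bin <- rownames(calibration)
  rownames(calibration) <- NULL
  list(variants = variants, calibration = calibration)
}
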