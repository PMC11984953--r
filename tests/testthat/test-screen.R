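# Genome-wide screen: per-variant verdicts, block-resampled fractions, and
# data-splitting validation.

test_that("per-variant verdicts follow the decision rule endpoints", {
  cfg <- screen_config()
  rec <- make_records(beta_a = c(0.2, 0.2, 0.5), beta_b = c(0.2, 0.2, -0.5),
                      se_a = c(0.1, 1e-6, 1e-6), se_b = c(0.1, 1e-6, 1e-6))
  cls <- classify_loci(rec, cfg)
  expect_identical(cls$preferred, c("additive", "additive", "gxe"))
})

test_that("verdicts agree with mse_pair on every record", {
  set.seed(101)
  cfg <- screen_config(noise_ratio_proxy = 1.7, omega_focal = 0.4)
  rec <- make_records(beta_a = rnorm(200, 0, 0.1), beta_b = rnorm(200, 0, 0.1),
                      se_a = runif(200, 0.01, 0.1), se_b = runif(200, 0.01, 0.1))
  cls <- classify_loci(rec, cfg)
  oracle <- vapply(seq_len(nrow(rec)), function(i) {
    va <- rec$se_a[i]^2
    mse_pair(decision_input(rec$beta_a[i], rec$beta_b[i], va,
                            va / cfg$noise_ratio_proxy,
                            cfg$omega_focal))$preferred
  }, character(1))
  expect_identical(cls$preferred, oracle)
})

test_that("focal context B swaps the roles of the two contexts", {
  rec <- make_records(beta_a = c(0.5, 0), beta_b = c(0, 0),
                      se_a = c(1e-5, 0.1), se_b = c(0.05, 0.1))
  cls_b <- classify_loci(rec, screen_config(focal_context = "B"))
  # variant 1: huge difference but the focal (B) se is 0.05 -> snr = 100 > 2
  expect_identical(cls_b$preferred[1], "gxe")
  expect_equal(cls_b$snr[1], (0.5 / 0.05)^2)
})

test_that("significance restriction changes composition, not verdicts", {
  set.seed(55)
  rec <- make_records(beta_a = rnorm(500, 0, 0.2), beta_b = rnorm(500, 0, 0.1),
                      se_a = runif(500, 0.01, 0.1), se_b = runif(500, 0.01, 0.1),
                      pval_a = runif(500)^4)
  cfg <- screen_config(sig_threshold = 0.01)
  full <- classify_loci(rec, cfg)
  sig <- classify_loci(rec, cfg, significant_only = TRUE)
  expect_true(all(sig$pval_a < 0.01))
  expect_identical(sig$preferred,
                   full$preferred[match(sig$variant_id, full$variant_id)])
})

test_that("records with missing SEs are dropped with a warning", {
  rec <- make_records(beta_a = c(0.1, 0.2), beta_b = c(0, 0),
                      se_a = c(0.05, NA), se_b = c(0.05, 0.05))
  expect_warning(cls <- classify_loci(rec, screen_config()), "dropping 1")
  expect_equal(nrow(cls), 1L)
})

test_that("below the critical noise ratio every variant prefers GxE", {
  set.seed(77)
  omega <- 0.5
  r <- critical_noise_ratio(omega) * 0.9
  cfg <- screen_config(noise_ratio_proxy = r, omega_focal = omega)
  rec <- make_records(beta_a = rnorm(300), beta_b = rnorm(300),
                      se_a = runif(300, 0.1, 1), se_b = runif(300, 0.1, 1),
                      block_id = rep(1:50, 6))
  fr <- fraction_gxe_preferred(rec, cfg, noise_corrected = FALSE)
  expect_equal(fr$percent, 100)
})

test_that("block-resampled fraction hits its endpoints and the strong-signal oracle", {
  cfg <- screen_config(seed = 9, n_block_draws = 10)
  # zero effect difference everywhere: 0% (noise correction makes snr <= 0)
  rec0 <- make_records(beta_a = rep(0.3, 200), beta_b = rep(0.3, 200),
                       se_a = rep(0.05, 200), se_b = rep(0.05, 200),
                       block_id = rep(1:40, 5))
  expect_equal(fraction_gxe_preferred(rec0, cfg)$percent, 0)

  # extreme amplification with tiny SEs: 100%
  rec1 <- make_records(beta_a = rnorm(200, 0, 1), beta_b = rep(0, 200),
                       se_a = rep(1e-4, 200), se_b = rep(1e-4, 200),
                       block_id = rep(1:40, 5))
  expect_equal(fraction_gxe_preferred(rec1, cfg)$percent, 100)

  expect_error(fraction_gxe_preferred(rec1[, setdiff(names(rec1), "block_id")],
                                      cfg),
               class = "gxe_missing_blocks")

  # strong-signal synthetic stats: fraction matches the rule applied to the
  # noiseless true effects (a one-sided regime, so plug-in noise cannot
  # flip verdicts)
  gen <- generate_summary_stats(summary_stat_config(
    n_variants = 4000, n_blocks = 400, null_fraction = 0, equal_share = 0,
    effect_sd = 0.2, n = 200000, m = 200000, seed = 31))
  truth_snr <- (gen$truth$beta_a - gen$truth$beta_b)^2 / gen$records$se_a^2
  oracle_pct <- 100 * mean(truth_snr > snr_threshold(0.5, 1))
  est <- fraction_gxe_preferred(gen$records, screen_config(seed = 2))
  expect_equal(est$percent, oracle_pct, tolerance = 0.05)
})

test_that("split validation is exact without noise and calibrated with it", {
  cfg <- screen_config()
  # identical train/holdout with zero noise: realized equals analytic margin
  set.seed(19)
  beta_a <- rnorm(50, 0, 0.3)
  beta_b <- rnorm(50, 0, 0.3)
  se <- rep(1e-8, 50)
  tr <- make_records(beta_a, beta_b, se, se)
  sv <- split_validate(tr, tr, cfg)
  analytic <- vapply(seq_len(50), function(i) {
    mse_pair(decision_input(beta_a[i], beta_b[i], 1e-16, 1e-16, 0.5))$margin
  }, numeric(1))
  # both noise terms are ~1e-16; the bias-squared term dominates
  expect_equal(sv$variants$realized_diff,
               0.25 * (beta_a - beta_b)^2, tolerance = 1e-6)
  expect_equal(sv$variants$predicted_diff, analytic, tolerance = 1e-6)

  # pure-null effects: mean predicted difference equals the variance penalty
  set.seed(20)
  j <- 40000
  va <- 0.004
  vb <- 0.006
  tr <- make_records(rnorm(j, 0, sqrt(va)), rnorm(j, 0, sqrt(vb)),
                     rep(sqrt(va), j), rep(sqrt(vb), j))
  ho <- make_records(rnorm(j, 0, sqrt(va)), rnorm(j, 0, sqrt(vb)),
                     rep(sqrt(va), j), rep(sqrt(vb), j))
  sv <- split_validate(tr, ho, cfg)
  penalty <- 0.25 * va + 0.25 * vb - va
  expect_equal(mean(sv$variants$predicted_diff), penalty, tolerance = 0.05)

  # calibration: binned realized means track predicted means. Binning on the
  # (noisy) predicted value induces a small regression-to-the-mean bias in
  # the edge bins, so the check is at high predicted signal-to-noise, per
  # bin against the paired-difference SE, with most (not all) bins required.
  set.seed(22)
  j <- 50000
  beta_a <- rnorm(j, 0, 0.3)
  beta_b <- beta_a + rnorm(j, 0, 0.3)   # real effect differences
  se_v <- rep(0.001, j)
  mk <- function() make_records(rnorm(j, beta_a, se_v), rnorm(j, beta_b, se_v),
                                se_v, se_v)
  sv <- split_validate(mk(), mk(), cfg)
  ok <- with(sv$calibration,
             abs(mean_realized - mean_predicted) < 3 * se_diff)
  expect_gte(mean(ok), 0.8)
  # and globally the paired means agree within Monte-Carlo error
  d <- sv$variants$realized_diff - sv$variants$predicted_diff
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(j))
})

test_that("split validation rejects unmatched variant ids", {
  tr <- make_records(0.1, 0.2, 0.05, 0.05)
  ho <- tr
  ho$variant_id <- "other"
  expect_error(split_validate(tr, ho, screen_config()),
               class = "gxe_unmatched_ids")
})
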