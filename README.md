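# gxetradeoff

Genetic effects on complex traits can depend on context — sex, diet, age,
exposures. Whether a genome-wide association study (GWAS) should *model*
that dependence is not obvious: estimating a separate effect per context
removes bias but inflates sampling variance. This package implements a
bias–variance decision framework for choosing, per variant and focal
context, between the **additive** (pooled) and **GxE** (context-stratified)
estimators of an allelic effect, together with two simulation studies that
show how single-variant thinking can mislead when context dependence is
polygenic.

It is aimed at statistical geneticists analysing two-context GWAS summary
statistics (e.g. sex-stratified effects) and at methodologists studying
gene-by-environment interaction, amplification, and context-aware polygenic
scores.

## The decision rule

For a biallelic variant observed in `n` individuals in context A and `m` in
context B, with context-specific effects `β_A`, `β_B` and stratified-OLS
sampling variances `V_A`, `V_B`, the pooled slope (after within-context
trait centering) is exactly

    β̂_A∪B = ω_A β̂_A + ω_B β̂_B,   ω_A ∝ n·H_A,  ω_B ∝ m·H_B,

where `H` is sample heterozygosity. For the focal context A,

    MSE(β̂_A)    = V_A                                (unbiased)
    MSE(β̂_A∪B) = ((ω_A−1)β_A + ω_B β_B)² + ω_A²V_A + ω_B²V_B

and the GxE estimator is preferred iff the second expression exceeds the
first. With equal heterozygosity this becomes a signal-to-noise rule:
prefer GxE iff

    (β_A − β_B)² / V_A  >  (1 + ω_A)/(1 − ω_A) − V_B/V_A,

and when the noise ratio `r = V_A/V_B` falls below
`r* = (1 − ω_A)/(1 + ω_A)` (= 1/3 at ω_A = 1/2) the GxE estimator is
preferred at any signal.

Around this core the package provides:

* `classify_loci()`, `fraction_gxe_preferred()`, `split_validate()` — a
  genome-wide screen of two-context summary statistics with LD-block
  resampling and data-splitting validation;
* `estimate_pi0()`, `compute_qvalues()` — Storey q-values;
* `run_gxdiet_sim()` — a pervasive-amplification gene-by-diet simulator
  with the four-way top-hit classification (no-effect / sugar-specific /
  control-specific / shared, plus an explicit ambiguous remainder);
* `mash_lite()`, `shrink_univariate()` — empirical-Bayes shrinkage with a
  mixture of zero-centered (bi)variate normal priors fit by EM;
* `run_experiment()` — polygenic-score simulations under partial
  amplification comparing four ascertainment/estimation strategies;
* `generate_summary_stats()`, `generate_se_surrogate()` — seeded synthetic
  stand-ins for external inputs, with truth tables for scoring.

A thin command-line front end ships at `inst/cli/gxe_tool.R` with
subcommands `decide`, `screen`, `qvalue`, `sim-gxdiet`, `sim-pgs`,
`shrink`, `synth`.

## Worked example

```r
library(gxetradeoff)

# Should a male-specific (focal-context) effect be estimated separately?
d <- mse_pair(decision_input(beta_a = 0.05, beta_b = 0.12,
                             var_a = 0.0004, var_b = 0.0004, omega_a = 0.5))
d
#> decision: prefer gxe (MSE additive 0.001425, MSE GxE 0.0004)
critical_noise_ratio(0.5)
#> [1] 0.3333333

# Genome-wide screen of synthetic sex-stratified summary statistics
gen <- generate_summary_stats(summary_stat_config(n_variants = 5000,
                                                  n_blocks = 500, seed = 7))
cfg <- screen_config(noise_ratio_proxy = 1, seed = 7)
fr  <- fraction_gxe_preferred(gen$records, cfg)
sprintf("%.2f%% of effects better estimated under GxE", fr$percent)
#> [1] "17.70% of effects better estimated under GxE"

# Pervasive amplification masquerading as diet-specific effects
res <- run_gxdiet_sim(diet_sim_config(n_variants = 20000, seed = 7))
res$summary
#>           category count share_significant
#> 1        no_effect 18892                NA
#> 2   sugar_specific   236        0.46732673
#> 3 control_specific    37        0.07326733
#> 4           shared   232        0.45940594
#> 5        ambiguous   603                NA
```

The first block says that with equal noise (`V_A = V_B = 0.0004`,
i.e. SE = 0.02) a true effect difference of 0.07 is large enough that the
stratified estimator has ~3.6× lower MSE. The last block is the package's
cautionary tale: the generative model contains *no* diet-specific variants
— every non-null effect acts under both diets, 1.4× stronger under sugar —
yet per-diet significance classification labels ~47% of its significant
variants "sugar-specific".

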