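# mrpipe

Two-sample Mendelian randomization (MR) pipelines on GWAS summary
statistics, for epidemiologists asking whether an exposure (for example an
air pollutant) causally affects disease risk when only published
summary-level association tables are available. The package covers the
full inference chain used in modern MR studies of environmental exposures
and autoimmune disease: instrument selection and quality control,
two-sample MR with sensitivity analyses, fixed-effects meta-analysis
across cohorts, multivariable MR, two-step MR mediation through plasma
proteins, Bayesian colocalization, and transcriptome-wide association
(TWAS) overlap with Fisher-combined p-values — plus seeded synthetic-data
generators with recorded ground truth so every stage can be validated
end-to-end without access to restricted GWAS data.

## The statistics at the core

With per-SNP effects γ̂ⱼ (SNP → exposure, SE σ_γⱼ) and Γ̂ⱼ (SNP → outcome,
SE σ_Γⱼ) for instruments j = 1…k:

- **Instrument QC.** Candidates at p < 5×10⁻⁶, greedily LD-clumped
  (r² < 0.001 within 10 Mb). Variance explained R²ⱼ = 2·EAF(1−EAF)(β/SE)²
  and strength Fⱼ = (R²ⱼ/K) / [(1−R²ⱼ)/(N−K−1)] with K = 1; instruments
  with F < 10 are dropped, as are instruments with genome-wide-significant
  outcome associations.
- **IVW.** β̂ = Σwⱼγ̂ⱼΓ̂ⱼ / Σwⱼγ̂ⱼ², wⱼ = 1/σ_Γⱼ², with multiplicative
  random-effects SE inflation max(1, √(Q/(k−1))) from Cochran's Q.
- **MR-Egger.** Weighted regression of Γ̂ on γ̂ with intercept after
  orienting γ̂ⱼ ≥ 0; the intercept estimates mean directional pleiotropy
  under InSIDE; t inference on k−2 df.
- **Weighted median.** Median of Wald ratios Γ̂ⱼ/γ̂ⱼ weighted by
  γ̂ⱼ²/σ_Γⱼ², SE by seeded parametric bootstrap; consistent when ≥ 50% of
  weight is valid.
- **BH-FDR tiers** per exposure across outcomes: *significant* q < 0.05,
  *suggestive* p < 0.05 ≤ q.
- **Fixed-effects meta-analysis**, **multivariable MR** (weighted multiple
  regression without intercept; lasso exposure selection via seeded
  cross-validation), and **total-vs-direct** mediation comparison.
- **Two-step mediation**: indirect effect β₁β₂ with delta-method SE
  √(β₁²σ₂² + β₂²σ₁²).
- **Colocalization**: per-SNP Wakefield log approximate Bayes factors
  combined into posteriors PP.H0…PP.H4 (shared causal variant when
  PP.H4 > 0.8), all sums in log space.
- **TWAS**: gene-level z = wᵀz / √(wᵀRw) from expression weights w and LD
  R; direction-concordant overlap genes ranked by Fisher's combined
  p-value, X = −2Σln p ~ χ²(2k).

## Worked example

```r
library(mrpipe)

sim  <- simulate_two_sample(sim_config(seed = 7))     # truth: beta = 0.3
ids  <- select_by_pvalue(sim$exposure, p_threshold = 5e-6)
pair <- harmonize_pair(sim$exposure, sim$outcome, ids)
pair <- drop_outcome_associated(pair)
fit  <- mr_fit(pair, seed = 42)
tidy(fit)
#> # A tibble: 3 × 10
#>   exposure outcome term            estimate std.error statistic p.value    or
#> 1 exposure outcome ivw                0.261    0.0901     2.90  0.00372  1.30
#> 2 exposure outcome egger              0.267    0.402      0.664 0.509    1.31
#> 3 exposure outcome weighted_median    0.243    0.135      1.80  0.0715   1.27
glance(fit)
#> # A tibble: 1 × 8
#>   exposure outcome n_snp q_stat  q_df q_pval egger_intercept egger_intercept_pval
#> 1 exposure outcome    69   67.9    68  0.480      -0.0000915                0.989
```

The generator planted a true causal log-OR of 0.3 with no pleiotropy; the
IVW estimate of 0.26 (OR 1.30, 95% CI 1.09–1.55) recovers it within one
standard error, all three estimators agree, Cochran's Q shows no excess
heterogeneity (p = 0.48), and the Egger intercept is indistinguishable
from zero — the pattern expected of a clean instrument set. Each result
row carries the OR-scale confidence interval, heterogeneity diagnostics
and (after `mr_fdr_tier()`) the FDR tier. `autoplot(pair)`,
`plot_mr_forest(fit)` and `plot_leave_one_out(leave_one_out(pair))` give
the standard diagnostic figures, and `run_pipeline(pipeline_config(seed =
1), "out/")` executes every stage on a fully simulated study and writes
the report tables.

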