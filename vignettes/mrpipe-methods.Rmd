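---
title: "Models and methods behind mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

# The causal model

All estimators in mrpipe operate on the two-sample summary-statistic
model. For instrument $j$ the SNP–outcome effect decomposes as

$$\Gamma_j = \beta\,\gamma_j + \alpha_j,$$

where $\gamma_j$ is the SNP–exposure effect, $\beta$ the causal effect of
interest (a log odds ratio per SD of exposure for binary outcomes), and
$\alpha_j$ a direct (pleiotropic) effect of the variant on the outcome.
Observed effects $\hat\gamma_j, \hat\Gamma_j$ carry known standard errors
from two non-overlapping GWAS. Identification requires the usual
instrumental-variable assumptions: relevance (enforced by the selection
and F-statistic filters), independence, and exclusion ($\alpha_j = 0$),
with the sensitivity estimators relaxing exclusion in different ways
(Egger: constant mean $\alpha$ under InSIDE; weighted median: at most
half the weight invalid).

# Instrument quality control

Candidates must pass $p < 5\times10^{-6}$ on the exposure — the relaxed
threshold used when few variants reach $5\times10^{-8}$; the comparison
is strict, so a p-value exactly at the threshold is excluded. Greedy LD
clumping then walks candidates in ascending p-value order (ties broken
lexicographically by variant id, which makes the output invariant to
input order) and keeps a variant only if no already-kept variant on the
same chromosome within 10 Mb has $r^2 \ge 0.001$ with it. Variant pairs
missing from the LD matrix are treated as unlinked with a warning,
because sparse LD files are the norm.

Two conventions for the per-instrument variance explained are
implemented:

- **verbatim**: $R^2 = 2\,\mathrm{EAF}(1-\mathrm{EAF})(\beta/SE)^2$. This
  textbook expression omits a sample-size normalization and exceeds 1 for
  strong instruments; such rows are flagged invalid and never silently
  clamped.
- **normalized**: $R^2 = z^2/(z^2 + N - K - 1)$, bounded in $(0,1)$ and
  giving $F \approx z^2$.

Both feed $F = (R^2/K)\,/\,[(1-R^2)/(N-K-1)]$ with $K = 1$ per
instrument; $F < 10$ is dropped (boundary kept). Instruments with
genome-wide-significant outcome associations ($p < 5\times10^{-8}$,
recomputed from $\Gamma/SE$) are excluded so instruments act on the
outcome only through the exposure.

# Harmonization

Variants are matched by id. Outcome rows whose alleles are swapped
relative to the exposure have their beta negated and EAF mirrored;
strand flips are resolved through complements. Palindromic (A/T, C/G)
variants cannot be resolved by labels: the strand is inferred from
effect-allele frequencies, and the variant is dropped whenever either
trait's EAF falls in the ambiguity band (0.42, 0.58), or when the
outcome EAF is missing. The band is configurable; the default mirrors
common two-sample MR practice.

# Estimators

**IVW** is weighted least squares of $\hat\Gamma$ on $\hat\gamma$ through
the origin with weights $1/\sigma_{\Gamma j}^2$. Heterogeneity is
Cochran's $Q$ on $k-1$ df; the random-effects SE multiplies the
fixed-effect SE by $\max(1, \sqrt{Q/(k-1)})$. The floor at 1 (so
under-dispersion never *shrinks* the SE) matches the behaviour of the
widely used implementations; `re_floor = FALSE` removes it. Inference is
normal. A single instrument falls back to the Wald ratio
$\hat\Gamma/\hat\gamma$ with first-order SE $\sigma_\Gamma/|\hat\gamma|$.

**MR-Egger** adds an intercept after orienting every instrument so
$\hat\gamma_j \ge 0$ — the orientation under which the intercept
estimates the mean directional pleiotropic effect. SEs are inflated by
the residual scale floored at 1 and inference uses $t_{k-2}$, mirroring
common practice (the orientation is applied to Egger only: IVW and the
weighted median are orientation-invariant, which is property-tested).

**Weighted median**: Wald ratios $b_j$ with normalized weights
$w_j \propto \hat\gamma_j^2/\sigma_{\Gamma j}^2$ are sorted; with
cumulative sums $S_j$ the percentile of $b_j$ is $p_j = S_j - w_j/2$ and
the estimate linearly interpolates $b$ at $p = 0.5$. The SE comes from a
parametric bootstrap (default 1,000 resamples of
$\hat\gamma_j, \hat\Gamma_j$ from normals at their SEs); the seed is
mandatory so results are reproducible.

**Leave-one-out** re-runs IVW dropping each instrument in turn and flags
sign flips and significance flips of the full-set estimate.

**FDR tiers**: Benjamini–Hochberg step-up q-values are computed within
one exposure's family of tests across all outcomes (the study design
this package mirrors uses 15 outcomes, and its published FDR column is
reproduced exactly by $m = 15$: the rank-1 q-values equal $15p$).
Results are *significant* at $q < 0.05$ and *suggestive* at
$p < 0.05 \le q$.

**Power** for a binary outcome uses the standard asymptotic
approximation
$\Phi(|\ln \mathrm{OR}|\sqrt{N R^2 K(1-K)} - z_{1-\alpha/2})$ with $K$
the case fraction and $R^2$ the summed instrument variance explained.

# Meta-analysis, multivariable MR and mediation

Fixed-effects pooling uses inverse-variance weights under the one-true-
effect assumption; its SE is never larger than the smallest input SE
(enforced as an invariant test). Multivariable MR regresses
$\hat\Gamma$ on the matrix of per-exposure $\hat\gamma$'s without
intercept, weights $1/\sigma_\Gamma^2$, SEs inflated by the residual
scale floored at 1. The instrument set is the union of per-exposure
selections, jointly re-clumped — the construction is not pinned down in
the study design this mirrors, and the union is the choice that keeps
every exposure identified. Collinear exposures are removed beforehand by
a weighted lasso with seeded 10-fold cross-validation and the 1-SE rule;
exactly duplicated columns are dropped structurally before the lasso
because the penalty can split a coefficient across perfect copies. At
least one exposure is always retained.

The total-versus-direct comparison reports
$\mathrm{gap} = \beta_{total} - \beta_{direct}$ with the conservative
independence SE $\sqrt{se_{total}^2 + se_{direct}^2}$; overlapping
samples are ignored and the output says so.

Two-step mediation gates step 1 (protein → disease) at BH-FDR < 0.05
across the protein panel per disease and step 2 (pollutant → protein) at
nominal $p < 0.05$ (the source design reports no explicit step-2
threshold). The indirect effect is $\beta_1\beta_2$ with delta-method SE
$\sqrt{\beta_1^2\sigma_2^2 + \beta_2^2\sigma_1^2}$.

# Colocalization

Per-SNP evidence is the Wakefield log approximate Bayes factor
$\tfrac12[\ln(1-r) + r z^2]$, $r = W/(V+W)$, with prior effect variance
$W = 0.04$ (SD 0.2) for quantitative traits and $0.0225$ (SD 0.15)
recommended for case-control log odds ratios. Regional hypothesis sums
use log-sum-exp throughout (single-SNP log ABFs can exceed 700), and
$S_3 = S_1S_2 - S_{12}$ is computed by log-space subtraction, set to
zero with a warning when only one SNP is shared. Priors default to
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ — the conventional defaults, as
the source design states none. A region is declared colocalized when
$\mathrm{PP.H4} > 0.8$. Swapping the traits swaps PP.H1/PP.H2 and fixes
the rest; posteriors always sum to 1 within $10^{-9}$ (both
property-tested).

# TWAS overlap

The gene-level statistic is $z = w^\top z_{GWAS} / \sqrt{w^\top R w}$
over the expression-model SNPs; it is invariant to rescaling $w$ and
antisymmetric under negation. A gene is an overlap gene for a pollutant
when both traits' TWAS p-values are below 0.05 *and* the z-statistics
share a sign ("same direction" is operationalized as equal sign, which
the source design leaves undefined). Pairwise evidence is Fisher's
combination of the two p-values (4 df); the across-pollutant summary
combines the four pairwise FCPs (8 df) rather than all five raw
p-values (10 df) — the 8-df rule reproduces the published combined
values to three significant figures and the 10-df rule does not, so it
is recorded as an inference and left config-visible. Ranks are dense and
1-based by ascending FCP. One caveat inherited from printed tables: a
combination recomputed from inputs rounded to three significant figures
can differ from the table's value in the third figure (observed ~0.2%
on one row); the tests assert accordingly.

# The synthetic-data generators

`simulate_two_sample()` draws summary statistics directly from their
sampling distributions rather than simulating individual-level
genotypes — adequate for every estimator here and orders of magnitude
faster. Defaults emulate the scale of the motivating study design:
exposure GWAS of 456,380, binary outcome GWAS of 200,000 with a 10% case
fraction, 80 instruments with true exposure $|z|$ uniform between the
selection threshold ($z_{5\times10^{-6}} \approx 4.56$) and 8, EAF
uniform on (0.05, 0.5) (the lower bound keeps the verbatim $R^2$ formula
away from its $\ge 1$ pathology in fixtures), and a true causal log OR
of 0.3. Instruments are coded on the exposure-increasing allele
($\gamma_j > 0$), the convention under which a directional pleiotropy
mean is well-defined; allele-level coding is then deterministically
shuffled on alternate outcome rows (plus a 10% palindromic fraction) so
harmonization is genuinely exercised.

Pleiotropy modes: `none`, `balanced` ($\alpha \sim N(0, sd^2)$),
`directional` ($N(\mu, sd^2)$, default $\mu = 0.05$), and
`inside_violating` ($\alpha$ correlated 0.5 with instrument strength).
`pleiotropy_frac` restricts pleiotropy to a subset of instruments. For
the invalid-instrument robustness scenario (30% invalid) the planted
pleiotropic effects use mean 0.005 with SD 0.0025 — the scale of the
per-SNP outcome effects themselves ($\beta\,E|\gamma| \approx 0.004$ at
these GWAS sizes). This is the comparable-effect-size regime of the MR
methods literature; effects an order of magnitude larger make every
invalid Wald ratio an extreme outlier relative to the per-ratio noise
(SD $\approx$ 0.8 here), a regime in which any finite-sample median is
biased and the robustness question degenerates.

`simulate_coloc_region()` builds AR(1) LD over 200 markers
($\rho = 0.9$) and draws marginal $z = R\lambda + \mathrm{MVN}(0, R)$,
with the causal non-centrality 8 (per-trait discovery power effectively
1) placed at a shared index, at two indices with $r^2 < 0.01$, or
nowhere. `simulate_mvmr()` plants block-structured instruments with true
direct effects (0.3, −0.2); `simulate_proteome_and_weights()` plants
pollutant → protein → disease chains ($\beta_2 = 0.3$,
$\beta_1 = 0.4$) in 3 of 20 panel proteins and sparse 5-SNP expression
weights whose planted genes are concordant-significant in both traits.

What the generators do *not* emulate: sample overlap between exposure
and outcome GWAS (the two-sample assumption is clean by construction),
LD from real reference panels, population stratification, relatedness,
winner's-curse in instrument selection, and binary-trait
non-collapsibility. Passing tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to those
real-data complications.

# Numerical choices and problem sizes

Determinism: every stochastic routine takes an explicit seed; the
pipeline derives per-stage child seeds from one global seed by fixed
offsets so adding a stage never perturbs earlier stages. All TSV output
uses fixed formatting with a commented provenance header, and reruns are
bit-identical.

The validation suite uses problem sizes chosen to bound each check's
Monte-Carlo error while keeping the default run fast: 500 replicates for
IVW coverage and Egger-intercept recovery, 2,000 for type-I error
(three MC SEs of 0.05 is ±0.015), 200 for weighted-median robustness
(bootstrap shortened to 200 resamples there), 200 regions per
colocalization configuration, 10,000 draws for the delta-method
cross-check, and 100 random instances for the clumping and
normal-equations oracles at tolerance $10^{-10}$.

# Known limitations

- The delta-method SE for $\beta_1\beta_2$ is first-order and assumes
  independent steps; it understates uncertainty when the same GWAS
  contributes to both.
- The power formula and the binary-outcome SE scaling
  $1/\sqrt{2\,\mathrm{EAF}(1-\mathrm{EAF})\,N\,K(1-K)}$ are asymptotic
  approximations on the log-OR scale.
- Colocalization assumes at most one causal variant per trait per
  region; multi-causal fine-mapping variants (SuSiE-style) are out of
  scope.
- No Steiger directionality filtering, MR-PRESSO outlier removal, or
  mode-based estimators; the estimator battery is IVW, Egger, weighted
  median, as in the design this package mirrors.
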