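mr_result_row <- function(pair, method, n_snp, beta, se, pval,
                          q_stat = NA_real_, q_df = NA_integer_,
                          q_pval = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_se = NA_real_,
                          egger_intercept_pval = NA_real_) {
  zc <- qnorm(0.975)
  out <- tibble(
    exposure = attr(pair, "exposure_name") %||% "exposure",
    outcome = attr(pair, "outcome_name") %||% "outcome",
    method = method, n_snp = as.integer(n_snp),
    beta = beta, se = se,
    or = exp(beta), ci_low = exp(beta - zc * se), ci_high = exp(beta + zc * se),
    pval = pval,
    q_stat = q_stat, q_df = as.integer(q_df), q_pval = q_pval,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_pval = egger_intercept_pval,
    fdr_q = NA_real_, tier = NA_character_
  )
  class(out) <- c("mr_result", class(out))
  out
}

#' Wald ratio: single-instrument causal estimate
#'
#' `beta = Gamma / gamma` with first-order standard error
#' `se = se_Gamma / |gamma|`.
#'
#' @param gamma,se_gamma SNP-exposure effect and its SE.
#' @param Gamma,se_Gamma SNP-outcome effect and its SE.
#' @return List with `beta` and `se`.
#' @export
mr_wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma) {
  if (any(gamma == 0)) abort("Wald ratio undefined for gamma = 0")
  list(beta = Gamma / gamma, se = se_Gamma / abs(gamma))
}

#' Inverse-variance weighted (IVW) two-sample MR
#'
#' Weighted regression of SNP-outcome on SNP-exposure effects through the
#' origin, weights `1/se_Gamma^2`. The causal estimate is
#' `sum(w*gamma*Gamma)/sum(w*gamma^2)` with fixed-effect standard error
#' `(sum(w*gamma^2))^(-1/2)`. Heterogeneity is summarized by Cochran's Q on
#' `n_snp - 1` degrees of freedom. Under the (default) multiplicative
#' random-effects model the SE is inflated by `sqrt(Q/(n_snp-1))`, floored
#' at 1; `re_floor = FALSE` removes the floor so under-dispersion shrinks
#' the SE. P-values are two-sided normal.
#'
#' @param pair An `mr_harmonized` tibble with at least 2 instruments (a
#'   single instrument falls back to the Wald ratio with a message).
#' @param random_effects Apply multiplicative overdispersion (default TRUE).
#' @param re_floor Floor the overdispersion factor at 1 (default TRUE).
#' @return One-row `mr_result` tibble.
#' @export
mr_ivw <- function(pair, random_effects = TRUE, re_floor = TRUE) {
  k <- nrow(pair)
  if (k < 2) {
    if (k == 0) abort("no instruments")
    message("single instrument: falling back to Wald ratio")
    wr <- mr_wald_ratio(pair$gamma, pair$se_gamma, pair$Gamma, pair$se_Gamma)
    return(mr_result_row(pair, "wald_ratio", 1, wr$beta, wr$se,
                         two_sided_p(wr$beta / wr$se)))
  }
  w <- 1 / pair$se_Gamma^2
  beta <- sum(w * pair$gamma * pair$Gamma) / sum(w * pair$gamma^2)
  se0 <- sum(w * pair$gamma^2)^-0.5
  q <- sum(w * (pair$Gamma - beta * pair$gamma)^2)
  q_df <- k - 1L
  scale <- sqrt(q / q_df)
  if (re_floor) scale <- max(1, scale)
  se <- if (random_effects) se0 * scale else se0
  mr_result_row(pair, "ivw", k, beta, se, two_sided_p(beta / se),
                q_stat = q, q_df = q_df,
                q_pval = pchisq(q, q_df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of SNP-outcome on SNP-exposure effects with an
#' intercept, weights `1/se_Gamma^2`, after orienting every instrument so
#' its exposure effect is non-negative. The slope is the pleiotropy-robust
#' causal estimate; the intercept estimates the average directional
#' pleiotropic effect (zero under no directional pleiotropy / InSIDE).
#' Standard errors are inflated by the residual scale floored at 1 and
#' inference uses the t distribution on `n_snp - 2` df.
#'
#' @param pair An `mr_harmonized` tibble with at least 3 instruments.
#' @return One-row `mr_result` tibble including the intercept test and
#'   Egger's Q on `n_snp - 2` df.
#' @export
mr_egger <- function(pair) {
  k <- nrow(pair)
  if (k < 3) abort("MR-Egger requires at least 3 instruments")
  flip <- sign(pair$gamma)
  flip[flip == 0] <- 1
  g <- pair$gamma * flip
  G <- pair$Gamma * flip
  w <- 1 / pair$se_Gamma^2

  # closed-form WLS with intercept; unit-information SEs inflated by the
  # residual scale floored at 1
  X <- cbind(1, g)
  xtwx_inv <- solve(crossprod(X, w * X))
  coefs <- unname(drop(xtwx_inv %*% crossprod(X, w * G)))
  resid <- G - drop(X %*% coefs)
  q <- sum(w * resid^2)
  q_df <- k - 2L
  infl <- max(1, sqrt(q / q_df))
  ses <- sqrt(diag(xtwx_inv)) * infl
  inter <- coefs[1]; slope <- coefs[2]
  inter_se <- ses[1]; slope_se <- ses[2]

  mr_result_row(pair, "egger", k, slope, slope_se,
                2 * pt(abs(slope / slope_se), df = q_df, lower.tail = FALSE),
                q_stat = q, q_df = q_df,
                q_pval = pchisq(q, q_df, lower.tail = FALSE),
                egger_intercept = inter, egger_intercept_se = inter_se,
                egger_intercept_pval =
                  2 * pt(abs(inter / inter_se), df = q_df, lower.tail = FALSE))
}

weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w)
  p <- s - w / 2
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median two-sample MR
#'
#' The weighted median of the per-SNP Wald ratios, with weights
#' proportional to `gamma^2 / se_Gamma^2`; consistent when at least half
#' the weight comes from valid instruments. The point estimate interpolates
#' the ratio at cumulative weight percentile 0.5 (percentiles
#' `S_j - w_j/2`). The SE comes from a seeded parametric bootstrap that
#' resamples `gamma` and `Gamma` from normal distributions with their
#' standard errors.
#'
#' @param pair An `mr_harmonized` tibble with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Mandatory integer seed for the bootstrap.
#' @return One-row `mr_result` tibble.
#' @export
mr_weighted_median <- function(pair, n_boot = 1000, seed) {
  k <- nrow(pair)
  if (k < 3) abort("weighted median requires at least 3 instruments")
  if (missing(seed) || is.null(seed)) abort("seed is required for the weighted-median bootstrap")
  b <- pair$Gamma / pair$gamma
  w <- pair$gamma^2 / pair$se_Gamma^2
  est <- weighted_median_point(b, w)

  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      g <- rnorm(k, pair$gamma, pair$se_gamma)
      G <- rnorm(k, pair$Gamma, pair$se_Gamma)
      ok <- g != 0
      weighted_median_point(G[ok] / g[ok], g[ok]^2 / pair$se_Gamma[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_result_row(pair, "weighted_median", k, est, se, two_sided_p(est / se))
}

#' Run the standard estimator battery on one harmonized pair
#'
#' @param pair An `mr_harmonized` tibble.
#' @param methods Any of `"ivw"`, `"egger"`, `"weighted_median"`.
#' @param seed Seed for the weighted-median bootstrap.
#' @param n_boot Bootstrap replicates for the weighted median.
#' @return An `mr_result` tibble, one row per method.
#' @export
mr_fit <- function(pair, methods = c("ivw", "egger", "weighted_median"),
                   seed = 1L, n_boot = 1000) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- lapply(methods, function(m) {
    switch(m,
      ivw = mr_ivw(pair),
      egger = mr_egger(pair),
      weighted_median = mr_weighted_median(pair, n_boot = n_boot, seed = seed)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mr_result", class(out))
  out
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates IVW `n_snp` times, omitting one instrument each time.
#' Flags are raised if any omission flips the sign of the estimate or moves
#' its p-value across 0.05 relative to the full-set fit.
#'
#' @param pair An `mr_harmonized` tibble with at least 3 instruments.
#' @return Tibble of class `mr_loo` with one row per dropped variant
#'   (`dropped_variant_id`, `beta`, `se`, `pval`) and attributes
#'   `full_fit`, `flag_sign_flip`, `flag_significance_flip`.
#' @export
leave_one_out <- function(pair) {
  if (nrow(pair) < 3) abort("leave-one-out requires at least 3 instruments")
  full <- mr_ivw(pair)
  rows <- purrr::map_dfr(seq_len(nrow(pair)), function(i) {
    fit <- mr_ivw(pair[-i, ])
    tibble(dropped_variant_id = pair$variant_id[i],
           beta = fit$beta, se = fit$se, pval = fit$pval)
  })
  attr(rows, "full_fit") <- full
  attr(rows, "flag_sign_flip") <- any(sign(rows$beta) != sign(full$beta))
  attr(rows, "flag_significance_flip") <-
    any((rows$pval < 0.05) != (full$pval < 0.05))
  class(rows) <- c("mr_loo", class(rows))
  rows
}

#' Benjamini-Hochberg FDR with significance tiers
#'
#' BH step-up q-values over one test family (in the study design: one
#' exposure's tests across all outcomes). Tier labels follow the rule:
#' `significant` when `q < 0.05`, `suggestive` when `p < 0.05 <= q`,
#' otherwise `null`.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param tiers Attach tier labels (default TRUE).
#' @param fdr_threshold,p_threshold Tier cutoffs (defaults 0.05).
#' @return Tibble with `pval`, `fdr_q` and (if requested) `tier`.
#' @export
bh_fdr <- function(pvals, tiers = TRUE, fdr_threshold = 0.05,
                   p_threshold = 0.05) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  q <- stats::p.adjust(pvals, method = "BH")
  out <- tibble(pval = pvals, fdr_q = q)
  if (tiers) {
    out$tier <- dplyr::case_when(
      q < fdr_threshold ~ "significant",
      pvals < p_threshold ~ "suggestive",
      TRUE ~ "null"
    )
  }
  out
}

#' Apply FDR tiers to a family of MR results
#'
#' @param results An `mr_result` tibble (typically one exposure across all
#'   outcomes, IVW rows).
#' @return The same tibble with `fdr_q` and `tier` filled in.
#' @export
mr_fdr_tier <- function(results, fdr_threshold = 0.05) {
  adj <- bh_fdr(results$pval, tiers = TRUE, fdr_threshold = fdr_threshold)
  results$fdr_q <- adj$fdr_q
  results$tier <- adj$tier
  results
}

#' Statistical power for a binary-outcome MR analysis
#'
#' Asymptotic power of the two-sided Wald test of the causal log odds
#' ratio:
#' `power = Phi(|ln OR| * sqrt(N * R2 * K * (1-K)) - z_{1-alpha/2})`
#' where `N` is the outcome sample size, `K` the case proportion and `R2`
#' the summed instrument variance explained in the exposure.
#'
#' @param n_outcome Outcome GWAS sample size.
#' @param case_proportion Proportion of cases, in (0, 1).
#' @param r2_sum Summed instrument variance explained, in [0, 1).
#' @param or_hypothesized Hypothesized odds ratio per SD of exposure.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0, 1).
#' @export
mr_power_binary <- function(n_outcome, case_proportion, r2_sum,
                            or_hypothesized, alpha = 0.05) {
  stopifnot(case_proportion > 0, case_proportion < 1,
            r2_sum >= 0, r2_sum < 1)
  if (r2_sum == 0) warn("r2_sum = 0: power equals the alpha-level tail")
  z_a <- qnorm(1 - alpha / 2)
  ncp <- abs(log(or_hypothesized)) *
    sqrt(n_outcome * r2_sum * case_proportion * (1 - case_proportion))
  pnorm(ncp - z_a)
}
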