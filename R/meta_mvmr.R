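#' Fixed-effects meta-analysis of cohort-level estimates
#'
#' Inverse-variance pooling under the assumption of one true effect size:
#' weights `1/se^2`, pooled estimate `sum(w*beta)/sum(w)`, pooled SE
#' `(sum(w))^(-1/2)`, and Cochran's Q across cohorts on `k - 1` df.
#'
#' @param estimates Data frame with columns `beta`, `se` and optionally
#'   `cohort`; at least two rows (a single row is passed through with a
#'   warning).
#' @return One-row tibble of class `mr_meta` with `pooled_beta`,
#'   `pooled_se`, `pooled_or`, `ci_low`, `ci_high`, `pooled_pval`,
#'   `het_q`, `het_df`, `het_pval`, `n_cohorts`; the input estimates are
#'   kept in the `estimates_in` attribute.
#' @export
meta_fixed <- function(estimates) {
  estimates <- as_tibble(estimates)
  stopifnot(all(c("beta", "se") %in% names(estimates)), all(estimates$se > 0))
  k <- nrow(estimates)
  if (k < 1) abort("no estimates to pool")
  if (k == 1) warn("single estimate: pooled result is a passthrough")
  w <- 1 / estimates$se^2
  pooled <- sum(w * estimates$beta) / sum(w)
  pooled_se <- sum(w)^-0.5
  q <- sum(w * (estimates$beta - pooled)^2)
  zc <- qnorm(0.975)
  out <- tibble(
    pooled_beta = pooled, pooled_se = pooled_se,
    pooled_or = exp(pooled),
    ci_low = exp(pooled - zc * pooled_se),
    ci_high = exp(pooled + zc * pooled_se),
    pooled_pval = two_sided_p(pooled / pooled_se),
    het_q = q, het_df = max(k - 1L, 0L),
    het_pval = if (k > 1) pchisq(q, k - 1, lower.tail = FALSE) else NA_real_,
    n_cohorts = k
  )
  attr(out, "estimates_in") <- estimates
  class(out) <- c("mr_meta", class(out))
  out
}

fit_mvmr_wls <- function(G_mat, Gamma, se_Gamma, exposure_names) {
  k <- nrow(G_mat)
  p <- ncol(G_mat)
  if (k <= p) abort("underdetermined model: need more instruments than exposures")
  w <- 1 / se_Gamma^2
  xtwx <- crossprod(G_mat, w * G_mat)
  if (qr(xtwx)$rank < p) {
    abort(paste0("rank-deficient design (collinear exposures); ",
                 "run lasso_select_exposures first"),
          class = "mrpipe_collinearity_error")
  }
  xtwx_inv <- solve(xtwx)
  coefs <- unname(drop(xtwx_inv %*% crossprod(G_mat, w * Gamma)))
  resid <- Gamma - drop(G_mat %*% coefs)
  sigma <- sqrt(sum(w * resid^2) / (k - p))
  ses <- sqrt(diag(xtwx_inv)) * max(1, sigma)
  zc <- qnorm(0.975)
  tibble(
    exposure = exposure_names,
    direct_beta = coefs, se = ses,
    or = exp(coefs),
    ci_low = exp(coefs - zc * ses), ci_high = exp(coefs + zc * ses),
    pval = two_sided_p(coefs / ses)
  )
}

#' Multivariable MR by weighted regression
#'
#' Estimates the direct effect of each exposure on the outcome, conditional
#' on the others, by weighted multiple regression without intercept of the
#' SNP-outcome effects on the matrix of per-exposure SNP effects (weights
#' `1/se_Gamma^2`; SEs inflated by the residual scale floored at 1; normal
#' p-values).
#'
#' The instrument set is the union of per-exposure selections, jointly
#' re-clumped, and every retained variant is harmonized across all
#' exposures and the outcome.
#'
#' @param exposures Named list of validated exposure association tibbles.
#' @param outcome Outcome association tibble.
#' @param ld LD matrix covering candidate instruments.
#' @param p_threshold,clump_r2,window_bp Instrument-selection parameters
#'   (defaults as in [build_instrument_set()]).
#' @return Tibble of class `mvmr_result`, one row per exposure, with
#'   attributes `n_snp`, `outcome_name`, `conditioned_on`.
#' @export
mvmr_ivw <- function(exposures, outcome, ld, p_threshold = 5e-6,
                     clump_r2 = 0.001, window_bp = 1e7) {
  stopifnot(is.list(exposures), !is.null(names(exposures)))
  # union of per-exposure candidates, jointly re-clumped on the pooled
  # table (smallest p across exposures drives the greedy order)
  cand <- unique(unlist(lapply(exposures, select_by_pvalue, p_threshold)))
  pooled <- dplyr::bind_rows(lapply(exposures, function(e) {
    e[e$variant_id %in% cand, c("variant_id", "chrom", "pos", "pval")]
  }))
  pooled <- pooled |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::slice_min(.data$pval, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  kept <- ld_clump(pooled$variant_id, pooled, ld, clump_r2, window_bp)

  # harmonize every exposure and the outcome to the first exposure's coding
  ref <- exposures[[1]]
  pairs <- lapply(exposures, function(e) {
    harmonize_pair(ref, e, intersect(kept, e$variant_id))
  })
  out_pair <- harmonize_pair(ref, outcome, kept)
  shared <- Reduce(intersect, c(lapply(pairs, function(p) p$variant_id),
                                list(out_pair$variant_id)))
  if (length(shared) <= length(exposures)) {
    abort("underdetermined model: need more instruments than exposures")
  }
  G_mat <- vapply(pairs, function(p) p$Gamma[match(shared, p$variant_id)],
                  numeric(length(shared)))
  colnames(G_mat) <- names(exposures)
  oi <- match(shared, out_pair$variant_id)

  res <- fit_mvmr_wls(G_mat, out_pair$Gamma[oi], out_pair$se_Gamma[oi],
                      names(exposures))
  res$outcome <- attr(outcome, "trait_name") %||% "outcome"
  attr(res, "n_snp") <- length(shared)
  attr(res, "outcome_name") <- attr(outcome, "trait_name") %||% "outcome"
  attr(res, "conditioned_on") <- names(exposures)[-1]
  class(res) <- c("mvmr_result", class(res))
  res
}

#' Fit a multivariable MR model from an already-harmonized design
#'
#' Lower-level interface for simulated or pre-joined data: a SNP-by-exposure
#' effect matrix, outcome effects and their SEs.
#'
#' @param design Numeric matrix (SNPs x exposures) of per-exposure SNP
#'   effects, with column names.
#' @param Gamma,se_Gamma Outcome effects and SEs aligned to `design` rows.
#' @return `mvmr_result` tibble as in [mvmr_ivw()].
#' @export
mvmr_fit <- function(design, Gamma, se_Gamma) {
  stopifnot(is.matrix(design), !is.null(colnames(design)),
            nrow(design) == length(Gamma), length(Gamma) == length(se_Gamma))
  res <- fit_mvmr_wls(design, Gamma, se_Gamma, colnames(design))
  res$outcome <- "outcome"
  attr(res, "n_snp") <- nrow(design)
  class(res) <- c("mvmr_result", class(res))
  res
}

#' Lasso feature selection over exposures
#'
#' Drops collinear or uninformative exposures before multivariable MR:
#' standardized weighted lasso path, penalty chosen by seeded 10-fold
#' cross-validation with the 1-SE rule; exposures with zero coefficient at
#' the chosen penalty are excluded. At least one exposure is always
#' retained (falling back to the smallest penalty on the path if the 1-SE
#' choice zeroes everything).
#'
#' @param design SNP-by-exposure effect matrix with column names.
#' @param response SNP-outcome effect vector.
#' @param weights Observation weights, typically `1/se_Gamma^2`.
#' @param seed Integer seed controlling fold assignment.
#' @param nfolds Cross-validation folds (default 10).
#' @return Character vector of retained exposure names.
#' @export
lasso_select_exposures <- function(design, response, weights = NULL,
                                   seed = 1L, nfolds = 10) {
  stopifnot(is.matrix(design), ncol(design) >= 2, !is.null(colnames(design)))
  weights <- weights %||% rep(1, nrow(design))

  # exactly collinear duplicates defeat the lasso (the penalty can split a
  # coefficient across copies); drop all but the first of each such group
  cors <- suppressWarnings(stats::cor(design))
  dup <- rep(FALSE, ncol(design))
  for (j in seq_len(ncol(design))[-1]) {
    dup[j] <- any(abs(cors[j, seq_len(j - 1)]) > 1 - 1e-10, na.rm = TRUE)
  }
  if (any(dup)) design <- design[, !dup, drop = FALSE]
  if (ncol(design) == 1) return(colnames(design))
  nfolds <- min(nfolds, nrow(design))
  foldid <- withr::with_seed(seed,
    sample(rep_len(seq_len(nfolds), nrow(design))))
  cv <- glmnet::cv.glmnet(design, response, weights = weights,
                          foldid = foldid, standardize = TRUE,
                          intercept = FALSE)
  pick <- function(lam) {
    cf <- as.matrix(stats::coef(cv, s = lam))[-1, , drop = FALSE]
    rownames(cf)[cf[, 1] != 0]
  }
  kept <- pick(cv$lambda.1se)
  if (length(kept) == 0) kept <- pick(min(cv$lambda))
  if (length(kept) == 0) kept <- colnames(design)[1]
  kept
}

#' Total-versus-direct effect comparison
#'
#' A gap between the total causal effect (univariable MR) and the direct
#' effect (multivariable MR conditioning on a mediator) indicates mediation
#' through the conditioned factor. The gap SE uses the conservative
#' independence approximation `sqrt(total_se^2 + direct_se^2)` (overlapping
#' samples ignored; flagged in the output).
#'
#' @param total_beta,total_se Univariable (total) estimate and SE.
#' @param direct_beta,direct_se Multivariable (direct) estimate and SE.
#' @param mediator_name Label of the conditioned mediator.
#' @return One-row tibble with `gap`, `gap_se`, `gap_pval`,
#'   `se_approximation = "independent"`.
#' @export
total_vs_direct <- function(total_beta, total_se, direct_beta, direct_se,
                            mediator_name) {
  gap <- total_beta - direct_beta
  gap_se <- sqrt(total_se^2 + direct_se^2)
  tibble(
    mediator_name = mediator_name,
    total_beta = total_beta, direct_beta = direct_beta,
    gap = gap, gap_se = gap_se,
    gap_pval = two_sided_p(gap / gap_se),
    se_approximation = "independent"
  )
}
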