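#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR result table
#'
#' Broom-style view of an `mr_result` tibble: one row per estimator with
#' standard column names (`term` = method, `estimate` = causal log OR,
#' `std.error`, `p.value`, OR-scale confidence bounds).
#'
#' @param x An `mr_result` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.mr_result <- function(x, ...) {
  tibble(
    exposure = x$exposure, outcome = x$outcome,
    term = x$method, estimate = x$beta, std.error = x$se,
    statistic = x$beta / x$se, p.value = x$pval,
    or = x$or, conf.low = x$ci_low, conf.high = x$ci_high
  )
}

#' @rdname tidy.mr_result
#' @export
glance.mr_result <- function(x, ...) {
  ivw <- x[x$method == "ivw", ]
  if (nrow(ivw) == 0) ivw <- x[1, ]
  egg <- x[x$method == "egger", ]
  tibble(
    exposure = ivw$exposure, outcome = ivw$outcome,
    n_snp = ivw$n_snp, q_stat = ivw$q_stat, q_df = ivw$q_df,
    q_pval = ivw$q_pval,
    egger_intercept = if (nrow(egg)) egg$egger_intercept else NA_real_,
    egger_intercept_pval = if (nrow(egg)) egg$egger_intercept_pval else NA_real_
  )
}

#' Tidy a colocalization result
#'
#' @param x A `coloc_result` object.
#' @param ... Unused.
#' @return Tibble with one row per hypothesis (`hypothesis`, `posterior`).
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(hypothesis = names(x$pp), posterior = unname(x$pp))
}

#' @rdname tidy.coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  tibble(nsnps = x$nsnps, lead_variant = x$lead_variant,
         pp_h4 = unname(x$pp["PP.H4"]), colocalized = x$colocalized)
}

#' Tidy a fixed-effects meta-analysis
#'
#' @param x An `mr_meta` one-row tibble.
#' @param ... Unused.
#' @export
tidy.mr_meta <- function(x, ...) {
  tibble(estimate = x$pooled_beta, std.error = x$pooled_se,
         p.value = x$pooled_pval, or = x$pooled_or,
         conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname tidy.mr_meta
#' @export
glance.mr_meta <- function(x, ...) {
  tibble(n_cohorts = x$n_cohorts, het_q = x$het_q, het_df = x$het_df,
         het_pval = x$het_pval)
}
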