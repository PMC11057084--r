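#' Classify pQTL variants as cis or trans
#'
#' A variant is cis when it lies on the encoding gene's chromosome within
#' +/- 1 Mb of the gene body (inclusive boundaries); otherwise trans.
#'
#' @param records Tibble with columns `chrom`, `pos`, `gene_chrom`,
#'   `gene_start`, `gene_end`.
#' @param window_bp Window size, default 1e6.
#' @return `records` with a logical `cis_flag` column.
#' @export
classify_cis_trans <- function(records, window_bp = 1e6) {
  records <- as_tibble(records)
  stopifnot(all(c("chrom", "pos", "gene_chrom", "gene_start", "gene_end")
                %in% names(records)))
  records$cis_flag <- records$chrom == records$gene_chrom &
    records$pos >= records$gene_start - window_bp &
    records$pos <= records$gene_end + window_bp
  records
}

#' Two-step MR mediation through plasma proteins
#'
#' Step 1 is a proteome-wide MR of protein levels on disease risk; proteins
#' surviving FDR < `fdr_threshold` across the panel are "risk proteins".
#' Step 2 estimates the effect of each pollutant on those risk proteins and
#' keeps pairs with `p < step2_p_threshold`. For each surviving
#' (pollutant, protein, disease) triple the mediated (indirect) effect is
#' `beta1 * beta2` — beta1 the protein-to-disease effect, beta2 the
#' pollutant-to-protein effect — with the delta-method standard error
#' `sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)` and a two-sided normal p.
#'
#' @param step1 Tibble of protein-to-disease MR results: columns `protein`,
#'   `disease`, `beta`, `se`, `pval`.
#' @param step2 Tibble of pollutant-to-protein MR results: columns
#'   `pollutant`, `protein`, `beta`, `se`, `pval`.
#' @param fdr_threshold Step-1 FDR gate (default 0.05), applied per disease
#'   across the protein panel.
#' @param step2_p_threshold Step-2 nominal p gate (default 0.05).
#' @return Tibble with one row per surviving triple: `pollutant`,
#'   `protein`, `disease`, `beta1`, `se1`, `beta2`, `se2`, `indirect`,
#'   `indirect_se`, `indirect_pval`, `step1_fdr_q`. Empty when nothing
#'   survives.
#' @export
two_step_mediation <- function(step1, step2, fdr_threshold = 0.05,
                               step2_p_threshold = 0.05) {
  step1 <- as_tibble(step1)
  step2 <- as_tibble(step2)
  step1 <- step1 |>
    dplyr::group_by(.data$disease) |>
    dplyr::mutate(step1_fdr_q = stats::p.adjust(.data$pval, "BH")) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$step1_fdr_q < fdr_threshold)
  step2 <- dplyr::filter(step2, .data$pval < step2_p_threshold,
                         .data$protein %in% step1$protein)
  if (nrow(step1) == 0 || nrow(step2) == 0) {
    return(tibble(pollutant = character(), protein = character(),
                  disease = character(), beta1 = numeric(), se1 = numeric(),
                  beta2 = numeric(), se2 = numeric(), indirect = numeric(),
                  indirect_se = numeric(), indirect_pval = numeric(),
                  step1_fdr_q = numeric()))
  }
  dplyr::inner_join(
    dplyr::select(step2, pollutant = "pollutant", protein = "protein",
                  beta2 = "beta", se2 = "se"),
    dplyr::select(step1, protein = "protein", disease = "disease",
                  beta1 = "beta", se1 = "se", step1_fdr_q = "step1_fdr_q"),
    by = "protein", relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      indirect = .data$beta1 * .data$beta2,
      indirect_se = sqrt(.data$beta1^2 * .data$se2^2 +
                           .data$beta2^2 * .data$se1^2),
      indirect_pval = two_sided_p(.data$indirect / .data$indirect_se)
    ) |>
    dplyr::select("pollutant", "protein", "disease", "beta1", "se1",
                  "beta2", "se2", "indirect", "indirect_se",
                  "indirect_pval", "step1_fdr_q")
}

#' Wakefield log approximate Bayes factor
#'
#' For a single variant with estimate `beta`, standard error `se` and prior
#' effect variance `prior_w`: with `V = se^2`, `z = beta/se`,
#' `r = prior_w / (V + prior_w)`, the log ABF is
#' `0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se Effect estimate(s) and SE(s); `se > 0`.
#' @param prior_w Prior variance of the true effect (> 0); conventionally
#'   0.04 (sd 0.2) for quantitative traits and 0.0225 (sd 0.15) for
#'   case-control log odds ratios.
#' @return Numeric vector of log ABFs.
#' @export
wakefield_labf <- function(beta, se, prior_w) {
  stopifnot(all(se > 0), prior_w > 0)
  v <- se^2
  z <- beta / se
  r <- prior_w / (v + prior_w)
  0.5 * (log(1 - r) + r * z^2)
}

#' Bayesian colocalization of two traits in one region
#'
#' Enumeration-based colocalization over a shared variant panel: per-SNP
#' Wakefield log ABFs for each trait are combined into the five regional
#' hypotheses — H0 no association, H1/H2 association with one trait only,
#' H3 two distinct causal variants, H4 one shared causal variant — with
#' priors `p1`, `p2` (per-SNP single-trait association) and `p12` (per-SNP
#' shared association). All sums of exponentials use log-sum-exp, so very
#' large Bayes factors are safe. A region colocalizes when `PP.H4 > 0.8`.
#'
#' @param trait1,trait2 Tibbles with columns `variant_id`, `beta`, `se`;
#'   the variant intersection is analyzed (mismatches logged via message).
#' @param p1,p2,p12 Prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_w1,prior_w2 Prior effect variances per trait (defaults
#'   0.04).
#' @return Object of class `coloc_result`: list with `nsnps`,
#'   `lead_variant` (largest combined ABF), `pp` (named numeric
#'   `PP.H0`..`PP.H4`, summing to 1), `priors`, `colocalized`.
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_w1 = 0.04, prior_w2 = 0.04) {
  trait1 <- as_tibble(trait1)
  trait2 <- as_tibble(trait2)
  shared <- intersect(trait1$variant_id, trait2$variant_id)
  if (length(shared) == 0) abort("no shared variants between traits")
  n_dropped <- (nrow(trait1) - length(shared)) + (nrow(trait2) - length(shared))
  if (n_dropped > 0) {
    message(n_dropped, " variant rows outside the shared panel were dropped")
  }
  t1 <- trait1[match(shared, trait1$variant_id), ]
  t2 <- trait2[match(shared, trait2$variant_id), ]
  l1 <- wakefield_labf(t1$beta, t1$se, prior_w1)
  l2 <- wakefield_labf(t2$beta, t2$se, prior_w2)

  ls1 <- logsumexp(l1)                  # log sum_i ABF1_i
  ls2 <- logsumexp(l2)                  # log sum_j ABF2_j
  ls12 <- logsumexp(l1 + l2)            # log sum_i ABF1_i ABF2_i
  if (length(shared) < 2) {
    warn("single shared variant: H3 undefined, computed with S3 = 0")
    ls3 <- -Inf
  } else {
    # S3 = S1*S2 - S12 (sum over i != j)
    ls3 <- logdiffexp(ls1 + ls2, ls12)
  }

  lpost <- c(
    0,
    log(p1) + ls1,
    log(p2) + ls2,
    log(p1) + log(p2) + ls3,
    log(p12) + ls12
  )
  pp <- exp(lpost - logsumexp(lpost))
  names(pp) <- paste0("PP.H", 0:4)

  structure(list(
    nsnps = length(shared),
    lead_variant = shared[which.max(l1 + l2)],
    pp = pp,
    priors = c(p1 = p1, p2 = p2, p12 = p12),
    prior_w = c(trait1 = prior_w1, trait2 = prior_w2),
    colocalized = unname(pp["PP.H4"] > 0.8)
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result> ", x$nsnps, " SNPs, lead ", x$lead_variant, "\n", sep = "")
  print(round(x$pp, 4))
  cat(if (x$colocalized) "colocalized (PP.H4 > 0.8)\n" else "not colocalized\n")
  invisible(x)
}

#' Extract a +/- window region around the lead cis variant
#'
#' Selects, from an association table, all variants on the lead variant's
#' chromosome within `window_bp` of it. The lead is the smallest-p variant
#' among `cis_ids` (ties by id).
#'
#' @param table Association tibble.
#' @param cis_ids Candidate lead ids (e.g. cis-pQTL for one protein).
#' @param window_bp Half-window, default 1e6.
#' @return List with `lead_variant` and `region` (the sub-table).
#' @export
extract_coloc_region <- function(table, cis_ids, window_bp = 1e6) {
  cand <- table[table$variant_id %in% cis_ids, ]
  if (nrow(cand) == 0) abort("no cis candidates present in table")
  cand <- cand[order(cand$pval, cand$variant_id), ]
  lead <- cand[1, ]
  region <- table[table$chrom == lead$chrom &
                    abs(table$pos - lead$pos) <= window_bp, ]
  list(lead_variant = lead$variant_id, region = region)
}
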