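#' Gene-level TWAS association from expression weights
#'
#' Combines GWAS z-scores through an expression model's SNP weights,
#' accounting for LD among the weight SNPs:
#' `z_twas = (w . z) / sqrt(w' R w)`, with a two-sided normal p-value.
#'
#' @param weights Tibble with columns `variant_id`, `weight` (and
#'   optionally a `gene` label attribute or column).
#' @param gwas_z Tibble with columns `variant_id`, `z`.
#' @param ld Signed LD matrix covering the weight variants.
#' @param gene,trait Labels carried into the result.
#' @return One-row tibble: `gene`, `trait`, `z_twas`, `pval`.
#' @export
twas_association <- function(weights, gwas_z, ld, gene = "gene",
                             trait = "trait") {
  weights <- as_tibble(weights)
  if ("gene" %in% names(weights) && length(unique(weights$gene)) == 1) {
    gene <- weights$gene[1]
  }
  if (any(!weights$variant_id %in% gwas_z$variant_id) ||
      any(!weights$variant_id %in% rownames(ld))) {
    abort("weight variants must be present in both gwas_z and ld")
  }
  w <- weights$weight
  if (all(w == 0)) abort("degenerate weights: all zero")
  z <- gwas_z$z[match(weights$variant_id, gwas_z$variant_id)]
  R <- ld[weights$variant_id, weights$variant_id, drop = FALSE]
  denom <- drop(t(w) %*% R %*% w)
  if (denom <= 1e-12) abort("degenerate weights: w'Rw <= 1e-12")
  z_twas <- sum(w * z) / sqrt(denom)
  tibble(gene = gene, trait = trait, z_twas = z_twas,
         pval = two_sided_p(z_twas))
}

#' Fisher's combined p-value
#'
#' `X = -2 * sum(log(p))` referred to a chi-square distribution with
#' `2 * length(p)` degrees of freedom (upper tail).
#'
#' @param pvals Numeric vector of p-values in (0, 1]; a zero is rejected
#'   (floor upstream at machine epsilon if needed).
#' @return The combined p-value.
#' @export
fisher_combined <- function(pvals) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    abort("p-values must lie in (0, 1]; floor zeros at .Machine$double.xmin upstream")
  }
  x <- -2 * sum(log(pvals))
  pchisq(x, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Direction-concordant TWAS overlap with Fisher-combined ranking
#'
#' A gene is an overlap gene for a pollutant when both its disease and
#' pollutant TWAS p-values fall below `alpha` and the two z-statistics
#' share a sign. Each surviving (gene, pollutant) pair gets
#' `fcp_pair = fisher_combined(disease_p, pollutant_p)` (4 df); genes
#' overlapping every pollutant also get `fcp_all`, the Fisher combination
#' of their pairwise FCPs (2 * n_pollutants df). Dense 1-based ranks are
#' assigned by ascending FCP within each pollutant column and for
#' `fcp_all`.
#'
#' @param disease_twas Tibble of per-gene disease TWAS results (`gene`,
#'   `z_twas`, `pval`).
#' @param pollutant_twas Named list of per-pollutant tibbles with the same
#'   columns.
#' @param alpha Per-trait significance gate (default 0.05).
#' @return Tibble with one row per (gene, pollutant) overlap: `gene`,
#'   `disease_p`, `pollutant`, `pollutant_p`, `fcp_pair`, `rank_pair`,
#'   `fcp_all`, `rank_all` (`fcp_all`/`rank_all` are NA unless the gene
#'   overlaps all pollutants).
#' @export
concordant_overlap_and_rank <- function(disease_twas, pollutant_twas,
                                        alpha = 0.05) {
  stopifnot(is.list(pollutant_twas), !is.null(names(pollutant_twas)))
  disease_twas <- as_tibble(disease_twas)

  pairs <- purrr::imap_dfr(pollutant_twas, function(pt, name) {
    joined <- dplyr::inner_join(
      dplyr::select(disease_twas, gene = "gene", z_disease = "z_twas",
                    disease_p = "pval"),
      dplyr::select(as_tibble(pt), gene = "gene", z_pollutant = "z_twas",
                    pollutant_p = "pval"),
      by = "gene"
    )
    joined <- dplyr::filter(
      joined,
      .data$disease_p < alpha, .data$pollutant_p < alpha,
      sign(.data$z_disease) == sign(.data$z_pollutant)
    )
    if (nrow(joined) == 0) return(NULL)
    joined$pollutant <- name
    joined$fcp_pair <- vapply(seq_len(nrow(joined)), function(i) {
      fisher_combined(c(joined$disease_p[i], joined$pollutant_p[i]))
    }, numeric(1))
    joined
  })
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(tibble(gene = character(), disease_p = numeric(),
                  pollutant = character(), pollutant_p = numeric(),
                  fcp_pair = numeric(), rank_pair = integer(),
                  fcp_all = numeric(), rank_all = integer()))
  }
  pairs <- pairs |>
    dplyr::group_by(.data$pollutant) |>
    dplyr::mutate(rank_pair = dplyr::dense_rank(.data$fcp_pair)) |>
    dplyr::ungroup()

  n_poll <- length(pollutant_twas)
  all_tbl <- pairs |>
    dplyr::group_by(.data$gene) |>
    dplyr::filter(dplyr::n() == n_poll) |>
    dplyr::summarise(fcp_all = fisher_combined(.data$fcp_pair),
                     .groups = "drop") |>
    dplyr::mutate(rank_all = dplyr::dense_rank(.data$fcp_all))

  pairs |>
    dplyr::left_join(all_tbl, by = "gene") |>
    dplyr::select("gene", "disease_p", "pollutant", "pollutant_p",
                  "fcp_pair", "rank_pair", "fcp_all", "rank_all") |>
    dplyr::arrange(.data$pollutant, .data$rank_pair)
}
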