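#' Select candidate instruments by exposure p-value
#'
#' Returns the variant ids whose exposure association p-value is strictly
#' below `p_threshold`, ordered by ascending p-value with ties broken
#' lexicographically by id. The default threshold of 5e-6 is the relaxed
#' genome-wide cut used when few variants reach 5e-8.
#'
#' @param table Validated association tibble.
#' @param p_threshold Strict upper bound on the p-value (default `5e-6`).
#' @return Character vector of variant ids (possibly empty).
#' @export
select_by_pvalue <- function(table, p_threshold = 5e-6) {
  table <- validate_association_table(table)
  hits <- table[table$pval < p_threshold, ]
  hits <- hits[order(hits$pval, hits$variant_id), ]
  hits$variant_id
}

#' Greedy LD clumping of candidate instruments
#'
#' Iterates candidates by ascending p-value (ties broken by id) and keeps a
#' candidate only if no already-kept variant on the same chromosome lies
#' within `window_bp` of it with pairwise r-squared at or above `clump_r2`.
#' Variant pairs absent from the LD matrix are treated as unlinked (r = 0);
#' a single warning reports how many lookups were missing.
#'
#' @param candidates Character vector of candidate variant ids.
#' @param table Association tibble supplying p-values and positions.
#' @param ld Signed LD correlation matrix (see [read_ld_matrix()]).
#' @param clump_r2 r-squared threshold, default 0.001.
#' @param window_bp Physical window in basepairs, default 10 Mb.
#' @return Character vector of retained ids, in selection order.
#' @export
ld_clump <- function(candidates, table, ld, clump_r2 = 0.001,
                     window_bp = 1e7) {
  if (length(candidates) == 0) return(character())
  missing_ids <- setdiff(candidates, table$variant_id)
  if (length(missing_ids) > 0) {
    abort(paste0("candidate(s) absent from table: ",
                 paste(missing_ids, collapse = ", ")))
  }
  rows <- table[match(candidates, table$variant_id), ]
  ord <- order(rows$pval, rows$variant_id)
  rows <- rows[ord, ]

  kept <- integer(0)
  n_missing_ld <- 0L
  for (i in seq_len(nrow(rows))) {
    ok <- TRUE
    for (j in kept) {
      if (rows$chrom[i] != rows$chrom[j]) next
      if (abs(rows$pos[i] - rows$pos[j]) > window_bp) next
      id_i <- rows$variant_id[i]; id_j <- rows$variant_id[j]
      if (id_i %in% rownames(ld) && id_j %in% rownames(ld)) {
        r <- ld[id_i, id_j]
      } else {
        r <- 0
        n_missing_ld <- n_missing_ld + 1L
      }
      if (r^2 >= clump_r2) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  if (n_missing_ld > 0) {
    warn(paste0(n_missing_ld, " LD lookup(s) missing; treated as r = 0"))
  }
  rows$variant_id[kept]
}

#' Variance explained and instrument F-statistic
#'
#' Computes, per instrument, the variance in the exposure explained by the
#' variant and the corresponding F-statistic
#' `F = (R2/K) / ((1 - R2) / (N - K - 1))` with `K = 1` SNP per instrument
#' by default. Two R-squared conventions are available:
#' \describe{
#'   \item{`"verbatim"`}{`R2 = 2*EAF*(1-EAF)*(beta/se)^2`. This textbook
#'     expression lacks a sample-size normalization and can exceed 1 for
#'     strong instruments; such rows are flagged `invalid = TRUE` (the
#'     computed value is kept, never clamped).}
#'   \item{`"normalized"`}{`R2 = z^2 / (z^2 + N - K - 1)` with
#'     `z = beta/se`, which is bounded in (0,1) and yields `F ~ z^2`.}
#' }
#'
#' @param eaf,beta,se Vectors of effect-allele frequency, effect and SE.
#' @param n Sample size(s); must exceed `k + 1`.
#' @param k Number of SNPs per instrument (default 1).
#' @param r2_formula `"verbatim"` (default) or `"normalized"`.
#' @return Tibble with columns `r2_explained`, `f_stat`, `invalid`.
#' @export
variance_explained_and_f <- function(eaf, beta, se, n, k = 1,
                                     r2_formula = c("verbatim", "normalized")) {
  r2_formula <- match.arg(r2_formula)
  stopifnot(all(eaf > 0 & eaf < 1), all(se > 0), all(n > k + 1))
  z <- beta / se
  r2 <- switch(r2_formula,
    verbatim = 2 * eaf * (1 - eaf) * z^2,
    normalized = z^2 / (z^2 + n - k - 1)
  )
  invalid <- r2 >= 1
  f <- ifelse(invalid, NA_real_, (r2 / k) / ((1 - r2) / (n - k - 1)))
  tibble(r2_explained = r2, f_stat = f, invalid = invalid)
}

#' Build an instrument set for one exposure
#'
#' Convenience wrapper chaining [select_by_pvalue()], [ld_clump()] and
#' [variance_explained_and_f()] into the per-instrument table consumed by
#' the MR estimators and the power calculation.
#'
#' @param table Exposure association tibble.
#' @param ld LD matrix covering the candidate variants.
#' @inheritParams select_by_pvalue
#' @inheritParams ld_clump
#' @inheritParams variance_explained_and_f
#' @param f_min Minimum F-statistic retained (default 10; `F = f_min` kept).
#' @return Tibble of class `mr_instruments` with one row per retained
#'   instrument (`variant_id`, `gamma`, `se_gamma`, `eaf`, `n`,
#'   `r2_explained`, `f_stat`) and a `selection_params` attribute.
#' @export
build_instrument_set <- function(table, ld, p_threshold = 5e-6,
                                 clump_r2 = 0.001, window_bp = 1e7,
                                 f_min = 10, k = 1,
                                 r2_formula = c("verbatim", "normalized")) {
  r2_formula <- match.arg(r2_formula)
  cand <- select_by_pvalue(table, p_threshold)
  kept <- ld_clump(cand, table, ld, clump_r2, window_bp)
  rows <- table[match(kept, table$variant_id), ]
  stats <- variance_explained_and_f(rows$eaf, rows$beta, rows$se, rows$n,
                                    k = k, r2_formula = r2_formula)
  out <- tibble(
    variant_id = rows$variant_id, gamma = rows$beta, se_gamma = rows$se,
    eaf = rows$eaf, n = rows$n,
    r2_explained = stats$r2_explained, f_stat = stats$f_stat,
    invalid = stats$invalid
  )
  out <- filter_weak(out, f_min = f_min)
  attr(out, "exposure_name") <- attr(table, "trait_name")
  attr(out, "selection_params") <- list(
    p_threshold = p_threshold, clump_r2 = clump_r2, clump_window_bp = window_bp,
    f_min = f_min, k_per_instrument = k, r2_formula = r2_formula
  )
  class(out) <- c("mr_instruments", class(out))
  out
}

#' Drop weak instruments by F-statistic
#'
#' Retains rows with `f_stat >= f_min`; rows flagged invalid (verbatim
#' R-squared at or above 1, so no finite F) are also dropped.
#'
#' @param instruments Instrument tibble with `f_stat` (and optionally
#'   `invalid`) columns.
#' @param f_min Threshold, default 10; the boundary `F = f_min` is kept.
#' @export
filter_weak <- function(instruments, f_min = 10) {
  drop <- is.na(instruments$f_stat) | instruments$f_stat < f_min
  if ("invalid" %in% names(instruments)) drop <- drop | instruments$invalid
  instruments[!drop, ]
}

#' Exclude instruments strongly associated with the outcome
#'
#' Instruments should act on the outcome only through the exposure; those
#' with genome-wide-significant outcome associations are removed. Outcome
#' p-values are recomputed two-sided from `Gamma / se_Gamma`.
#'
#' @param pair An `mr_harmonized` tibble.
#' @param outcome_p_threshold Exclusion threshold, default `5e-8` (strict
#'   `<`; a threshold of 0 removes nothing).
#' @return The filtered `mr_harmonized` tibble; removals appended to the
#'   harmonization log as `dropped-outcome-associated`.
#' @export
drop_outcome_associated <- function(pair, outcome_p_threshold = 5e-8) {
  p_out <- two_sided_p(pair$Gamma / pair$se_Gamma)
  drop <- p_out < outcome_p_threshold
  if (any(drop)) {
    log <- attr(pair, "harmonization_log") %||%
      tibble(variant_id = character(), action = character())
    log <- dplyr::bind_rows(log, tibble(variant_id = pair$variant_id[drop],
                                        action = "dropped-outcome-associated"))
    out <- pair[!drop, ]
    attr(out, "harmonization_log") <- log
    out
  } else {
    pair
  }
}

#' Check instrument F-statistics against a published supplement
#'
#' Reads one or more instrument tables (TSV with at least an `F` or
#' `f_stat` column; extra columns ignored) such as a study's supplementary
#' instrument listings, recomputes F from `eaf`, `beta`/`gamma`, `se` and
#' `n` columns when present, and returns the observed range.
#'
#' @param paths Character vector of TSV paths.
#' @return List with `f_min`, `f_max`, `n_instruments`.
#' @export
check_instrument_f_range <- function(paths) {
  if (length(paths) == 0) {
    abort("no instrument supplement files provided")
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("instrument supplement file(s) not found: ",
                 paste(missing, collapse = ", ")))
  }
  fs <- unlist(lapply(paths, function(p) {
    tbl <- read_mrpipe_tsv(p)
    names(tbl) <- tolower(names(tbl))
    fcol <- intersect(c("f_stat", "f", "fstat", "f.statistic"), names(tbl))[1]
    if (is.na(fcol)) abort(paste0("no F-statistic column in ", p))
    tbl[[fcol]]
  }))
  list(f_min = min(fs), f_max = max(fs), n_instruments = length(fs))
}
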