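ASSOC_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")

#' Validate a GWAS summary-statistics table
#'
#' Checks the schema and per-row invariants of an association table:
#' nine required columns, single-base distinct alleles, `se > 0`,
#' `eaf` strictly inside (0, 1), `pval` in (0, 1], `pos >= 1`, and unique
#' `variant_id`. Offending rows are reported with their 1-based row numbers.
#'
#' @param tbl A data frame of per-variant associations.
#' @return `tbl` as a tibble, invisibly unchanged, if valid.
#' @export
validate_association_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  missing <- setdiff(ASSOC_COLS, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "mrpipe_schema_error")
  }
  if (nrow(tbl) == 0) return(tbl)

  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      abort(paste0(what, " in row(s): ", paste(idx, collapse = ", ")),
            class = "mrpipe_validation_error")
    }
  }
  bases <- c("A", "C", "G", "T")
  bad(!(tbl$effect_allele %in% bases) | !(tbl$other_allele %in% bases),
      "allele not a single base A/C/G/T")
  bad(tbl$effect_allele == tbl$other_allele, "effect_allele equals other_allele")
  bad(!is.finite(tbl$se) | tbl$se <= 0, "se must be > 0")
  bad(!is.na(tbl$eaf) & (tbl$eaf <= 0 | tbl$eaf >= 1), "eaf must be in (0,1)")
  bad(!is.finite(tbl$pval) | tbl$pval <= 0 | tbl$pval > 1, "pval must be in (0,1]")
  bad(tbl$pos < 1, "pos must be >= 1")
  dup <- duplicated(tbl$variant_id)
  bad(dup, "duplicate variant_id")
  tbl
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated association table (gzip-transparent), optionally
#' renaming columns via `column_map`, validates it, and attaches the trait
#' name and type as attributes. Lines starting with `#` are treated as
#' comments.
#'
#' @param path Path to a TSV (optionally gzipped).
#' @param trait_name Trait label carried through downstream results.
#' @param trait_type `"binary"` (beta on the log-odds scale) or
#'   `"quantitative"` (beta in SD units).
#' @param column_map Optional named character vector mapping required column
#'   names to the names used in the file, e.g. `c(variant_id = "SNP")`.
#' @return A validated tibble with attributes `trait_name` and `trait_type`.
#' @export
read_association_table <- function(path, trait_name,
                                   trait_type = c("binary", "quantitative"),
                                   column_map = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- read_mrpipe_tsv(path)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      if (column_map[[std]] %in% names(tbl)) {
        names(tbl)[names(tbl) == column_map[[std]]] <- std
      }
    }
  }
  tbl <- validate_association_table(tbl)
  tbl$chrom <- as.character(tbl$chrom)
  attr(tbl, "trait_name") <- trait_name
  attr(tbl, "trait_type") <- trait_type
  tbl
}

#' Write a GWAS summary-statistics table
#'
#' @param tbl Validated association tibble.
#' @param path Output TSV path.
#' @param seed Optional seed recorded in the commented header line.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(tbl, path, seed = NULL) {
  write_mrpipe_tsv(tbl[ASSOC_COLS], path, seed = seed)
}

#' Read / write an LD correlation matrix
#'
#' The on-disk dialect is a square TSV: a header row of variant ids, a
#' leading id column, and signed correlations `r` (not r-squared) in the
#' body. Validation requires symmetry, a unit diagonal, `|r| <= 1`, and
#' positive semi-definiteness (smallest eigenvalue >= -1e-8).
#'
#' @param path TSV path.
#' @return A numeric matrix with variant ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  tbl <- read_mrpipe_tsv(path)
  ids <- as.character(tbl[[1]])
  r <- as.matrix(tbl[, -1, drop = FALSE])
  dimnames(r) <- list(ids, ids)
  validate_ld_matrix(r)
}

#' @rdname read_ld_matrix
#' @param r Square signed-correlation matrix with variant-id dimnames.
#' @param seed Optional seed recorded in the header comment.
#' @export
write_ld_matrix <- function(r, path, seed = NULL) {
  validate_ld_matrix(r)
  tbl <- as_tibble(r)
  tbl <- dplyr::bind_cols(tibble(variant_id = rownames(r)), tbl)
  write_mrpipe_tsv(tbl, path, seed = seed)
}

#' @rdname read_ld_matrix
#' @export
validate_ld_matrix <- function(r) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) abort("LD matrix must be square")
  if (is.null(rownames(r))) abort("LD matrix must carry variant ids as dimnames")
  if (max(abs(r - t(r))) > 1e-8) abort("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) abort("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + 1e-8) abort("LD entries must satisfy |r| <= 1")
  ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) abort(paste0("LD matrix not positive semi-definite: min eigenvalue ", ev))
  r
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) unname(COMPLEMENT[a1] == a2)

#' Align exposure and outcome effects on the same effect allele
#'
#' Restricts to the requested instruments, matches variants by id, and
#' reorients outcome effects so both traits are expressed per copy of the
#' exposure's effect allele. When outcome alleles are swapped the outcome
#' beta is negated and its EAF replaced by `1 - eaf`; strand flips are
#' resolved through allele complements. Palindromic (A/T, C/G) variants are
#' strand-inferred from the effect-allele frequencies and dropped when
#' either trait's EAF falls inside `palindrome_band` (or when the outcome
#' EAF is missing). Instruments absent from the outcome are dropped and
#' logged.
#'
#' @param exposure,outcome Validated association tibbles
#'   (see [read_association_table()]).
#' @param instrument_ids Character vector of instrument variant ids; must be
#'   a subset of the exposure table's ids.
#' @param palindrome_band Ambiguity band for palindromic EAFs, default
#'   `c(0.42, 0.58)`.
#' @return A tibble of class `mr_harmonized` with columns `variant_id`,
#'   `gamma`, `se_gamma`, `Gamma`, `se_Gamma`, `eaf`, `n_exposure`,
#'   `n_outcome`, plus attributes `exposure_name`, `outcome_name`, and
#'   `harmonization_log` (a tibble of per-variant actions: kept / flipped /
#'   dropped-palindromic / dropped-missing / dropped-irreconcilable).
#' @export
harmonize_pair <- function(exposure, outcome, instrument_ids,
                           palindrome_band = c(0.42, 0.58)) {
  exposure <- validate_association_table(exposure)
  outcome_name <- attr(outcome, "trait_name") %||% "outcome"
  exposure_name <- attr(exposure, "trait_name") %||% "exposure"
  outcome <- validate_association_table(outcome)
  if (!all(instrument_ids %in% exposure$variant_id)) {
    abort("instrument_ids must be a subset of the exposure table's variant ids")
  }

  exp_rows <- exposure[match(instrument_ids, exposure$variant_id), ]
  out_idx <- match(instrument_ids, outcome$variant_id)

  log_action <- character(length(instrument_ids))
  keep <- logical(length(instrument_ids))
  Gamma <- se_Gamma <- n_out <- rep(NA_real_, length(instrument_ids))

  in_band <- function(f) !is.na(f) & f > palindrome_band[1] & f < palindrome_band[2]

  for (i in seq_along(instrument_ids)) {
    if (is.na(out_idx[i])) {
      log_action[i] <- "dropped-missing"
      next
    }
    e <- exp_rows[i, ]
    o <- outcome[out_idx[i], ]
    pal <- is_palindromic(e$effect_allele, e$other_allele)

    orientation <- NA_character_
    if (o$effect_allele == e$effect_allele && o$other_allele == e$other_allele) {
      orientation <- "same"
    } else if (o$effect_allele == e$other_allele && o$other_allele == e$effect_allele) {
      orientation <- "swapped"
    } else {
      oc_eff <- unname(COMPLEMENT[o$effect_allele])
      oc_oth <- unname(COMPLEMENT[o$other_allele])
      if (oc_eff == e$effect_allele && oc_oth == e$other_allele) {
        orientation <- "same"
      } else if (oc_eff == e$other_allele && oc_oth == e$effect_allele) {
        orientation <- "swapped"
      }
    }
    if (is.na(orientation)) {
      log_action[i] <- "dropped-irreconcilable"
      next
    }

    if (pal) {
      # allele labels cannot fix the strand: infer from EAF concordance
      if (is.na(o$eaf) || in_band(e$eaf) || in_band(o$eaf)) {
        log_action[i] <- "dropped-palindromic"
        next
      }
      # same orientation should put both EAFs on the same side of 0.5
      same_side <- (e$eaf < 0.5) == (o$eaf < 0.5)
      orientation <- if (same_side) "same" else "swapped"
    }

    if (orientation == "same") {
      Gamma[i] <- o$beta
      log_action[i] <- "kept"
    } else {
      Gamma[i] <- -o$beta
      log_action[i] <- "flipped"
    }
    se_Gamma[i] <- o$se
    n_out[i] <- o$n
    keep[i] <- TRUE
  }

  out <- tibble(
    variant_id = instrument_ids[keep],
    gamma = exp_rows$beta[keep],
    se_gamma = exp_rows$se[keep],
    Gamma = Gamma[keep],
    se_Gamma = se_Gamma[keep],
    eaf = exp_rows$eaf[keep],
    n_exposure = exp_rows$n[keep],
    n_outcome = n_out[keep]
  )
  attr(out, "exposure_name") <- exposure_name
  attr(out, "outcome_name") <- outcome_name
  attr(out, "harmonization_log") <- tibble(variant_id = instrument_ids,
                                           action = log_action)
  class(out) <- c("mr_harmonized", class(out))
  out
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat("<mr_harmonized> ", attr(x, "exposure_name"), " -> ",
      attr(x, "outcome_name"), ", ", nrow(x), " instruments\n", sep = "")
  NextMethod()
}

#' Construct a harmonized pair from already-aligned effects
#'
#' Convenience constructor for data whose alleles are known to be aligned
#' (e.g. simulated effects): wraps a data frame with columns `variant_id`,
#' `gamma`, `se_gamma`, `Gamma`, `se_Gamma` (and optionally `eaf`,
#' `n_exposure`, `n_outcome`) as an `mr_harmonized` tibble.
#'
#' @param df Data frame of aligned per-variant effects.
#' @param exposure,outcome Trait labels.
#' @return An `mr_harmonized` tibble.
#' @export
as_mr_harmonized <- function(df, exposure = "exposure", outcome = "outcome") {
  df <- as_tibble(df)
  if (!"n_exposure" %in% names(df)) df$n_exposure <- NA_real_
  if (!"n_outcome" %in% names(df)) df$n_outcome <- NA_real_
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  attr(df, "exposure_name") <- exposure
  attr(df, "outcome_name") <- outcome
  class(df) <- c("mr_harmonized", class(df))
  df
}
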