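# In-code fixtures shared across test files. Everything is generated at
# test time; no binary data on disk.

tiny_assoc_table <- function(trait_name = "trait", trait_type = "binary") {
  tbl <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(1000L, 200000L, 5000L),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.30, 0.45, 0.12),
    beta = c(0.10, -0.05, 0.20),
    se = c(0.02, 0.01, 0.04),
    pval = c(5.7e-7, 6.2e-7, 5.7e-7),
    n = c(10000L, 10000L, 10000L)
  )
  attr(tbl, "trait_name") <- trait_name
  attr(tbl, "trait_type") <- trait_type
  tbl
}

# harmonized pair from bare vectors (already-aligned effects)
make_pair <- function(gamma, Gamma, se_gamma = rep(0.01, length(gamma)),
                      se_Gamma = rep(0.1, length(gamma))) {
  mrpipe::as_mr_harmonized(tibble::tibble(
    variant_id = sprintf("rs%d", seq_along(gamma)),
    gamma = gamma, se_gamma = se_gamma,
    Gamma = Gamma, se_Gamma = se_Gamma
  ))
}

# random correlation matrix with unit diagonal (PSD by construction)
random_corr <- function(n, seed) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n * n), n)
    r <- stats::cov2cor(crossprod(a) + diag(n) * 0.05)
    ids <- sprintf("rs%d", seq_len(n))
    dimnames(r) <- list(ids, ids)
    r
  })
}

# exhaustive oracle for greedy clumping: validates a proposed solution
# against the constraint definition rather than re-running the algorithm
clump_solution_valid <- function(kept, table, ld, clump_r2, window_bp) {
  rows <- table[match(table$variant_id, table$variant_id), ]
  pos <- setNames(table$pos, table$variant_id)
  chrom <- setNames(table$chrom, table$variant_id)
  pval <- setNames(table$pval, table$variant_id)
  conflict <- function(a, b) {
    chrom[a] == chrom[b] &&
      abs(pos[a] - pos[b]) <= window_bp &&
      ld[a, b]^2 >= clump_r2
  }
  # every kept pair must be constraint-free
  for (a in kept) for (b in kept) {
    if (a != b && conflict(a, b)) return(FALSE)
  }
  # every dropped variant must conflict with a kept variant of smaller
  # (or equal-with-earlier-id) p-value
  dropped <- setdiff(table$variant_id, kept)
  for (d in dropped) {
    ok <- any(vapply(kept, function(k) {
      conflict(d, k) && (pval[k] < pval[d] ||
                           (pval[k] == pval[d] && k < d))
    }, logical(1)))
    if (!ok) return(FALSE)
  }
  TRUE
}
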