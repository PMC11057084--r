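#' Simulation configuration
#'
#' Central parameter object for all generators. Defaults emulate the scale
#' of the study design this package targets: a quantitative exposure GWAS
#' of ~450k individuals with ~80 sub-genome-wide instruments, binary
#' outcome GWAS of ~200k with a 10% case fraction, effects on the log-odds
#' scale, and ~1 Mb LD regions of 200 markers.
#'
#' @param seed Mandatory integer seed.
#' @param n_snp Number of instruments in a two-sample scenario.
#' @param n_exposure_sample,n_outcome_sample GWAS sample sizes.
#' @param outcome_case_proportion Case fraction of the binary outcome.
#' @param eaf_range Uniform range for effect-allele frequencies; the lower
#'   bound of 0.05 keeps the textbook variance-explained formula away from
#'   its >= 1 pathology in fixtures.
#' @param true_beta True causal effect of exposure on outcome (log OR per
#'   SD of exposure).
#' @param pleiotropy_mode `"none"`, `"balanced"`, `"directional"` or
#'   `"inside_violating"` (pleiotropy correlated 0.5 with instrument
#'   strength).
#' @param pleiotropy_mean,pleiotropy_sd Mean/SD of direct pleiotropic
#'   effects where applicable.
#' @param pleiotropy_frac Fraction of instruments carrying pleiotropy
#'   (default 1; e.g. 0.3 plants a 30% invalid-instrument scenario).
#' @param instrument_z_min,instrument_z_max Uniform range of true exposure
#'   |z|; the default minimum is the two-sided z at p = 5e-6, so planted
#'   instruments clear the selection threshold in expectation.
#' @param palindrome_frac Fraction of variants given A/T or C/G coding.
#' @param outcome_allele_shuffle Deterministically swap allele coding on
#'   alternate outcome rows to exercise harmonization (default TRUE).
#' @param n_region_snp,ar1_rho,region_n_sample,lead_z,causal_config
#'   Colocalization-region parameters: markers per region, AR(1) LD
#'   correlation, per-trait sample size, non-centrality of the causal
#'   variant's z, and `"shared"` / `"distinct"` / `"null_one_trait"` /
#'   `"null_both"`.
#' @param n_exposures,mvmr_direct_betas,mvmr_block_size,cross_loading,
#'   duplicate_exposure Multivariable-scenario parameters: number of
#'   exposures, their true direct effects, instruments per exposure block,
#'   relative strength of cross-loadings, and whether to append a
#'   duplicated exposure column (exercises lasso selection).
#' @param n_proteins,n_mediators,beta1,se1,beta2,se2 Proteome-panel
#'   parameters: panel size, number of planted pollutant-protein-disease
#'   chains, protein-to-disease and pollutant-to-protein effects and the
#'   summary-level SEs at which they are observed.
#' @param n_weight_snps SNPs per gene expression-weight model.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_snp = 80,
                       n_exposure_sample = 456380,
                       n_outcome_sample = 200000,
                       outcome_case_proportion = 0.1,
                       eaf_range = c(0.05, 0.5),
                       true_beta = 0.3,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violating"),
                       pleiotropy_mean = 0.05,
                       pleiotropy_sd = 0.05,
                       pleiotropy_frac = 1,
                       instrument_z_min = qnorm(1 - 5e-6 / 2),
                       instrument_z_max = 8,
                       palindrome_frac = 0.1,
                       outcome_allele_shuffle = TRUE,
                       n_region_snp = 200,
                       ar1_rho = 0.9,
                       region_n_sample = 20000,
                       lead_z = 8,
                       causal_config = c("shared", "distinct",
                                         "null_one_trait", "null_both"),
                       n_exposures = 2,
                       mvmr_direct_betas = c(0.3, -0.2),
                       mvmr_block_size = 30,
                       cross_loading = 0,
                       duplicate_exposure = FALSE,
                       n_proteins = 20,
                       n_mediators = 3,
                       beta1 = 0.4, se1 = 0.08,
                       beta2 = 0.3, se2 = 0.06,
                       n_weight_snps = 5) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(n_snp >= 2, n_exposure_sample >= 2, n_outcome_sample >= 2,
            abs(ar1_rho) < 1)
  cfg <- list(
    seed = as.integer(seed), n_snp = n_snp,
    n_exposure_sample = n_exposure_sample,
    n_outcome_sample = n_outcome_sample,
    outcome_case_proportion = outcome_case_proportion,
    eaf_range = eaf_range, true_beta = true_beta,
    pleiotropy_mode = match.arg(pleiotropy_mode),
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    pleiotropy_frac = pleiotropy_frac,
    instrument_z_min = instrument_z_min,
    instrument_z_max = instrument_z_max,
    palindrome_frac = palindrome_frac,
    outcome_allele_shuffle = outcome_allele_shuffle,
    n_region_snp = n_region_snp, ar1_rho = ar1_rho,
    region_n_sample = region_n_sample, lead_z = lead_z,
    causal_config = match.arg(causal_config),
    n_exposures = n_exposures, mvmr_direct_betas = mvmr_direct_betas,
    mvmr_block_size = mvmr_block_size, cross_loading = cross_loading,
    duplicate_exposure = duplicate_exposure,
    n_proteins = n_proteins, n_mediators = n_mediators,
    beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
    n_weight_snps = n_weight_snps
  )
  class(cfg) <- "sim_config"
  cfg
}

NONPALINDROMIC_PAIRS <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("C", "G"))

# variant ids and coordinates spaced > 10 Mb apart so default clumping
# never prunes planted instruments
variant_scaffold <- function(n) {
  tibble(
    variant_id = sprintf("rs%06d", seq_len(n)),
    chrom = as.character(rep_len(1:22, n)),
    pos = 1e6 + (seq_len(n) - 1) %/% 22 * 2e7 + (seq_len(n) - 1) %% 22
  )
}

draw_alleles <- function(n, palindrome_frac) {
  pal <- runif(n) < palindrome_frac
  pick <- function(pairs, k) {
    idx <- sample.int(length(pairs), k, replace = TRUE)
    flip <- runif(k) < 0.5
    t(vapply(seq_len(k), function(i) {
      p <- pairs[[idx[i]]]
      if (flip[i]) rev(p) else p
    }, character(2)))
  }
  out <- matrix("", n, 2)
  if (any(!pal)) out[!pal, ] <- pick(NONPALINDROMIC_PAIRS, sum(!pal))
  if (any(pal)) out[pal, ] <- pick(PALINDROMIC_PAIRS, sum(pal))
  out
}

#' Simulate a two-sample GWAS summary-statistic pair with known truth
#'
#' Generates exposure and outcome association tables under the linear
#' causal model `Gamma_j = beta * gamma_j + alpha_j`, sampling summary
#' statistics directly from their asymptotic distributions. Planted
#' instruments have true exposure |z| uniform on
#' `[instrument_z_min, instrument_z_max]`; pleiotropic effects `alpha_j`
#' follow `pleiotropy_mode` and hit a `pleiotropy_frac` subset. Alternate
#' outcome rows are allele-swapped (beta negated, EAF mirrored) so the
#' pair exercises harmonization.
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` association tibbles and
#'   `truth` (true beta, per-SNP true gamma and alpha, pleiotropy regime,
#'   seed).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_snp
    scaf <- variant_scaffold(n)
    eaf <- runif(n, config$eaf_range[1], config$eaf_range[2])
    alleles <- draw_alleles(n, config$palindrome_frac)

    # instruments are coded on the exposure-increasing allele (gamma > 0),
    # the orientation under which directional pleiotropy has a fixed sign
    se_g <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_exposure_sample)
    z_true <- runif(n, config$instrument_z_min, config$instrument_z_max)
    gamma_true <- z_true * se_g
    gamma_hat <- gamma_true + rnorm(n, 0, se_g)

    alpha <- rep(0, n)
    hit <- seq_len(n) <= ceiling(config$pleiotropy_frac * n)
    m <- config$pleiotropy_mode
    if (m == "balanced") {
      alpha[hit] <- rnorm(sum(hit), 0, config$pleiotropy_sd)
    } else if (m == "directional") {
      alpha[hit] <- rnorm(sum(hit), config$pleiotropy_mean, config$pleiotropy_sd)
    } else if (m == "inside_violating") {
      zg <- as.numeric(scale(gamma_true[hit]))
      e <- rnorm(sum(hit))
      alpha[hit] <- config$pleiotropy_mean +
        config$pleiotropy_sd * (0.5 * zg + sqrt(0.75) * e)
    }

    kq <- config$outcome_case_proportion * (1 - config$outcome_case_proportion)
    se_G <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_outcome_sample * kq)
    Gamma_true <- config$true_beta * gamma_true + alpha
    Gamma_hat <- Gamma_true + rnorm(n, 0, se_G)

    exposure <- dplyr::bind_cols(scaf, tibble(
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = gamma_hat, se = se_g,
      pval = two_sided_p(gamma_hat / se_g),
      n = config$n_exposure_sample
    ))
    attr(exposure, "trait_name") <- "exposure"
    attr(exposure, "trait_type") <- "quantitative"

    swap <- config$outcome_allele_shuffle & (seq_len(n) %% 2 == 0)
    outcome <- dplyr::bind_cols(scaf, tibble(
      effect_allele = ifelse(swap, alleles[, 2], alleles[, 1]),
      other_allele = ifelse(swap, alleles[, 1], alleles[, 2]),
      eaf = ifelse(swap, 1 - eaf, eaf),
      beta = ifelse(swap, -Gamma_hat, Gamma_hat),
      se = se_G,
      pval = two_sided_p(Gamma_hat / se_G),
      n = config$n_outcome_sample
    ))
    attr(outcome, "trait_name") <- "outcome"
    attr(outcome, "trait_type") <- "binary"

    list(
      exposure = exposure, outcome = outcome,
      truth = list(true_beta = config$true_beta, gamma_true = gamma_true,
                   alpha = alpha, pleiotropy_mode = m,
                   swapped_rows = which(swap), seed = config$seed)
    )
  })
}

#' Truth-aligned harmonized pair from a two-sample simulation
#'
#' Builds the `mr_harmonized` pair directly from a [simulate_two_sample()]
#' result using the generator's record of which outcome rows were
#' allele-swapped, bypassing allele-based harmonization. Useful in
#' estimator-property simulations where harmonization itself is not under
#' study (it is exercised and tested separately).
#'
#' @param sim A [simulate_two_sample()] result.
#' @return An `mr_harmonized` tibble covering every simulated variant.
#' @export
truth_aligned_pair <- function(sim) {
  n <- length(sim$truth$gamma_true)
  swap <- seq_len(n) %in% sim$truth$swapped_rows
  as_mr_harmonized(tibble(
    variant_id = sim$exposure$variant_id,
    gamma = sim$exposure$beta, se_gamma = sim$exposure$se,
    Gamma = ifelse(swap, -sim$outcome$beta, sim$outcome$beta),
    se_Gamma = sim$outcome$se,
    eaf = sim$exposure$eaf,
    n_exposure = sim$exposure$n, n_outcome = sim$outcome$n
  ))
}

ar1_matrix <- function(n, rho) {
  r <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
  ids <- sprintf("rs%06d", seq_len(n))
  dimnames(r) <- list(ids, ids)
  r
}

#' Simulate an LD-structured colocalization region for two traits
#'
#' Builds an AR(1) LD matrix over `n_region_snp` markers and draws marginal
#' z-scores `z = R lambda + MVN(0, R)`, where `lambda` places the causal
#' non-centrality `lead_z` at the causal index of each trait according to
#' `causal_config` (shared index, distinct indices with pairwise r^2 <
#' 0.01, or nulls). Betas and SEs are backed out with unit-variance
#' scaling (`se = 1/sqrt(n)`).
#'
#' @param config A [sim_config()].
#' @return List with `trait1`, `trait2` (tibbles: `variant_id`, `beta`,
#'   `se`, `z`), `ld`, and `truth` (causal indices and config echo).
#' @export
simulate_coloc_region <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    m <- config$n_region_snp
    R <- ar1_matrix(m, config$ar1_rho)
    ids <- rownames(R)
    L <- chol(R)

    # distinct causal indices far enough apart that r^2 < 0.01
    min_gap <- ceiling(log(0.1) / log(abs(config$ar1_rho))) + 1
    idx1 <- idx2 <- NA_integer_
    cc <- config$causal_config
    if (cc == "shared") {
      idx1 <- idx2 <- ceiling(m / 2)
    } else if (cc == "distinct") {
      idx1 <- max(1, ceiling(m / 2) - min_gap)
      idx2 <- min(m, idx1 + 2 * min_gap)
    } else if (cc == "null_one_trait") {
      idx1 <- ceiling(m / 2)
    }

    draw <- function(idx) {
      lam <- rep(0, m)
      if (!is.na(idx)) lam[idx] <- config$lead_z
      z <- drop(R %*% lam) + drop(crossprod(L, rnorm(m)))
      n <- config$region_n_sample
      tibble(variant_id = ids, beta = z / sqrt(n), se = 1 / sqrt(n), z = z)
    }
    list(
      trait1 = draw(idx1), trait2 = draw(idx2), ld = R,
      truth = list(causal_index_trait1 = idx1, causal_index_trait2 = idx2,
                   causal_config = cc, min_gap = min_gap, seed = config$seed)
    )
  })
}

#' Simulate a multi-exposure instrument set with known direct effects
#'
#' Block-structured instruments: each exposure owns a block of
#' `mvmr_block_size` SNPs loading strongly on it, with optional weak
#' cross-loadings on the others; the outcome is built from the true direct
#' effects. Optionally appends a duplicate of the first exposure to
#' exercise lasso-based exposure selection.
#'
#' @param config A [sim_config()].
#' @return List with `exposures` (named list of association tibbles),
#'   `outcome`, `ld` (identity over the scaffold), `design` (observed
#'   SNP-by-exposure effect matrix), `Gamma`, `se_Gamma`, and `truth`.
#' @export
simulate_mvmr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    p <- config$n_exposures
    bs <- config$mvmr_block_size
    n <- p * bs
    betas <- rep_len(config$mvmr_direct_betas, p)
    scaf <- variant_scaffold(n)
    eaf <- runif(n, config$eaf_range[1], config$eaf_range[2])
    se_g <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_exposure_sample)

    gamma_true <- matrix(0, n, p)
    for (e in seq_len(p)) {
      block <- ((e - 1) * bs + 1):(e * bs)
      zs <- runif(bs, config$instrument_z_min, config$instrument_z_max) *
        sample(c(-1, 1), bs, replace = TRUE)
      gamma_true[block, e] <- zs * se_g[block]
      if (config$cross_loading > 0) {
        others <- setdiff(seq_len(p), e)
        gamma_true[block, others] <- gamma_true[block, others] +
          config$cross_loading * rnorm(bs * length(others)) * se_g[block]
      }
    }
    gamma_hat <- gamma_true + rnorm(n * p, 0, se_g)  # recycles by column

    kq <- config$outcome_case_proportion * (1 - config$outcome_case_proportion)
    se_G <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_outcome_sample * kq)
    Gamma_true <- drop(gamma_true %*% betas)
    Gamma_hat <- Gamma_true + rnorm(n, 0, se_G)

    names_e <- paste0("exposure_", seq_len(p))
    alleles <- matrix(rep(c("A", "G"), each = n), n, 2)
    mk_table <- function(b, s, nm, type) {
      t <- dplyr::bind_cols(scaf, tibble(
        effect_allele = alleles[, 1], other_allele = alleles[, 2],
        eaf = eaf, beta = b, se = s, pval = two_sided_p(b / s),
        n = config$n_exposure_sample
      ))
      attr(t, "trait_name") <- nm
      attr(t, "trait_type") <- type
      t
    }
    exposures <- lapply(seq_len(p), function(e) {
      mk_table(gamma_hat[, e], se_g, names_e[e], "quantitative")
    })
    names(exposures) <- names_e
    outcome <- mk_table(Gamma_hat, se_G, "outcome", "binary")

    design <- gamma_hat
    colnames(design) <- names_e
    if (config$duplicate_exposure) {
      design <- cbind(design, exposure_dup = design[, 1])
    }
    ld <- diag(n)
    dimnames(ld) <- list(scaf$variant_id, scaf$variant_id)

    list(
      exposures = exposures, outcome = outcome, ld = ld,
      design = design, Gamma = Gamma_hat, se_Gamma = se_G,
      truth = list(direct_betas = setNames(betas, names_e),
                   gamma_true = gamma_true, seed = config$seed)
    )
  })
}

#' Simulate a proteome panel with planted mediation chains and TWAS weights
#'
#' Emulates a plasma-protein pQTL panel and gene expression-weight sets:
#' `n_proteins` genes each with a cis lead variant, of which `n_mediators`
#' carry a planted pollutant-to-protein-to-disease chain (`beta2`, `beta1`
#' observed at summary-level SEs `se2`, `se1`). Expression weights are
#' sparse over each gene's region; disease and pollutant z-score tables are
#' built so planted genes are direction-concordant and significant in both
#' TWAS.
#'
#' @param config A [sim_config()].
#' @return List with `proteins` (gene coordinates and lead-variant fields,
#'   cis/trans flagged), `step1` and `step2` MR-style result tables,
#'   `weights` (named list of per-gene weight tibbles), `disease_z`,
#'   `pollutant_z`, `ld`, and `truth` (planted protein/gene names).
#' @export
simulate_proteome_and_weights <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    np <- config$n_proteins
    nm <- min(config$n_mediators, np)
    prot <- paste0("PROT", sprintf("%03d", seq_len(np)))
    planted <- prot[seq_len(nm)]

    gene_start <- 1e6 + (seq_len(np) - 1) * 5e6
    proteins <- tibble(
      protein = prot,
      gene_chrom = as.character(rep_len(1:22, np)),
      gene_start = gene_start, gene_end = gene_start + 5e4,
      variant_id = paste0("rslead", sprintf("%03d", seq_len(np))),
      chrom = as.character(rep_len(1:22, np)),
      pos = gene_start + sample(-9e5:9e5, np, replace = TRUE)
    )
    proteins <- classify_cis_trans(proteins)

    b1 <- ifelse(prot %in% planted, config$beta1, 0)
    step1 <- tibble(
      protein = prot, disease = "disease",
      beta = rnorm(np, b1, config$se1), se = config$se1
    )
    step1$pval <- two_sided_p(step1$beta / step1$se)

    b2 <- ifelse(prot %in% planted, config$beta2, 0)
    step2 <- tibble(
      pollutant = "pollutant", protein = prot,
      beta = rnorm(np, b2, config$se2), se = config$se2
    )
    step2$pval <- two_sided_p(step2$beta / step2$se)

    # gene expression weights and trait z-scores: planted genes get a
    # concordant signal in both traits through the same weighted direction
    k <- config$n_weight_snps
    ld <- diag(k * np)
    ids <- sprintf("rsw%05d", seq_len(k * np))
    dimnames(ld) <- list(ids, ids)
    weights <- list()
    disease_z <- pollutant_z <- tibble(variant_id = ids, z = rnorm(k * np))
    pollutant_z$z <- rnorm(k * np)
    for (i in seq_len(np)) {
      rows <- ((i - 1) * k + 1):(i * k)
      w <- rnorm(k)
      weights[[prot[i]]] <- tibble(gene = prot[i], variant_id = ids[rows],
                                   weight = w)
      if (prot[i] %in% planted) {
        # target twas z ~ 5 in both traits, same sign
        u <- w / sqrt(sum(w^2))
        disease_z$z[rows] <- 5 * u + rnorm(k, 0, 0.2)
        pollutant_z$z[rows] <- 5 * u + rnorm(k, 0, 0.2)
      }
    }
    list(
      proteins = proteins, step1 = step1, step2 = step2,
      weights = weights, disease_z = disease_z, pollutant_z = pollutant_z,
      ld = ld,
      truth = list(planted_proteins = planted,
                   beta1 = config$beta1, beta2 = config$beta2,
                   indirect = config$beta1 * config$beta2,
                   seed = config$seed)
    )
  })
}
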