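#' Default pipeline configuration
#'
#' Assembles the full config for [run_pipeline()]: every analysis
#' threshold at its study default, a global seed, and simulate-blocks
#' describing the synthetic scenario for each stage. Any block set to
#' `NULL` makes the pipeline skip that stage. The config can equivalently
#' be read from a YAML file with the same structure.
#'
#' @param seed Global seed; per-stage child seeds are derived from it by
#'   fixed offsets so adding a stage never perturbs earlier stages.
#' @param n_outcomes Number of simulated disease outcomes in the TSMR
#'   stage (the BH-FDR family size).
#' @param thresholds Named list overriding any of: `p_threshold` (5e-6),
#'   `clump_r2` (0.001), `clump_window_bp` (1e7), `f_min` (10),
#'   `outcome_p_exclusion` (5e-8), `pqtl_p` (1e-5), `fdr` (0.05),
#'   `pph4` (0.8), `alpha` (0.05).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_outcomes = 15,
                            thresholds = list()) {
  th <- utils::modifyList(list(
    p_threshold = 5e-6, clump_r2 = 0.001, clump_window_bp = 1e7,
    f_min = 10, outcome_p_exclusion = 5e-8, pqtl_p = 1e-5,
    fdr = 0.05, pph4 = 0.8, alpha = 0.05
  ), thresholds)
  cfg <- list(
    seed = as.integer(seed),
    thresholds = th,
    tsmr = list(n_outcomes = n_outcomes, true_beta = 0.3, n_snp = 80),
    meta = list(n_cohorts = 2),
    mvmr = list(n_exposures = 2),
    mediation = list(n_proteins = 20, n_mediators = 3),
    coloc = list(causal_config = "shared"),
    twas = list()
  )
  class(cfg) <- "pipeline_config"
  cfg
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config(seed = cfg$seed %||% 1L,
                          n_outcomes = cfg$tsmr$n_outcomes %||% 15,
                          thresholds = cfg$thresholds %||% list())
  for (blk in c("tsmr", "meta", "mvmr", "mediation", "coloc", "twas")) {
    if (!is.null(cfg[[blk]])) {
      base[[blk]] <- utils::modifyList(base[[blk]], cfg[[blk]])
    } else if (blk %in% names(cfg)) {
      base[[blk]] <- NULL           # explicit null disables the stage
    }
  }
  base
}

#' Run the full summary-statistics inference pipeline
#'
#' Executes, in order: instrument selection and TSMR with FDR tiers across
#' simulated outcomes; fixed-effects meta-analysis across cohorts;
#' multivariable MR; two-step protein mediation; colocalization; and TWAS
#' overlap. Stages whose config block is `NULL` are skipped and logged.
#' Every output is a TSV under `out_dir` plus a `run_log.tsv` recording
#' the package version, seed, thresholds and per-stage row counts.
#'
#' @param config A [pipeline_config()] or the path to a YAML file with the
#'   same structure.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list of the stage result objects.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  seed <- config$seed
  log_rows <- list()
  results <- list()
  note <- function(stage, status, n) {
    log_rows[[length(log_rows) + 1]] <<- tibble(stage = stage,
                                                status = status, rows = n)
  }

  # --- TSMR across outcomes -------------------------------------------
  if (!is.null(config$tsmr)) {
    n_out <- config$tsmr$n_outcomes
    per_outcome <- purrr::map_dfr(seq_len(n_out), function(i) {
      # plant a real effect in a third of the outcomes
      beta_i <- if (i %% 3 == 1) config$tsmr$true_beta else 0
      cfg <- sim_config(seed = seed + 100L + i, n_snp = config$tsmr$n_snp,
                        true_beta = beta_i)
      sim <- simulate_two_sample(cfg)
      ids <- select_by_pvalue(sim$exposure, th$p_threshold)
      pair <- harmonize_pair(sim$exposure, sim$outcome, ids)
      pair <- drop_outcome_associated(pair, th$outcome_p_exclusion)
      fit <- mr_fit(pair, seed = seed + 200L + i)
      fit$outcome <- paste0("disease_", sprintf("%02d", i))
      fit$true_beta <- beta_i
      fit
    })
    ivw_rows <- per_outcome[per_outcome$method == "ivw", ]
    ivw_rows <- mr_fdr_tier(ivw_rows, fdr_threshold = th$fdr)
    per_outcome$fdr_q[per_outcome$method == "ivw"] <- ivw_rows$fdr_q
    per_outcome$tier[per_outcome$method == "ivw"] <- ivw_rows$tier
    write_mrpipe_tsv(per_outcome, file.path(out_dir, "tsmr_results.tsv"), seed)

    sens <- per_outcome[per_outcome$method %in% c("ivw", "egger"),
                        c("exposure", "outcome", "method", "q_stat", "q_df",
                          "q_pval", "egger_intercept", "egger_intercept_pval")]
    write_mrpipe_tsv(sens, file.path(out_dir, "sensitivity.tsv"), seed)
    results$tsmr <- per_outcome
    note("tsmr", "ok", nrow(per_outcome))
  } else note("tsmr", "skipped", 0L)

  # --- fixed-effects meta across cohorts ------------------------------
  if (!is.null(config$meta)) {
    ests <- purrr::map_dfr(seq_len(config$meta$n_cohorts), function(cht) {
      cfg <- sim_config(seed = seed + 300L + cht, true_beta = 0.3)
      sim <- simulate_two_sample(cfg)
      ids <- select_by_pvalue(sim$exposure, th$p_threshold)
      pair <- harmonize_pair(sim$exposure, sim$outcome, ids)
      fit <- mr_ivw(pair)
      tibble(cohort = paste0("cohort_", cht), beta = fit$beta, se = fit$se)
    })
    meta <- meta_fixed(ests)
    write_mrpipe_tsv(as_tibble(meta), file.path(out_dir, "meta.tsv"), seed)
    results$meta <- meta
    note("meta", "ok", nrow(meta))
  } else note("meta", "skipped", 0L)

  # --- multivariable MR ------------------------------------------------
  if (!is.null(config$mvmr)) {
    cfg <- sim_config(seed = seed + 400L,
                      n_exposures = config$mvmr$n_exposures)
    sim <- simulate_mvmr(cfg)
    kept <- lasso_select_exposures(sim$design, sim$Gamma,
                                   weights = 1 / sim$se_Gamma^2,
                                   seed = seed + 401L)
    fit <- mvmr_fit(sim$design[, kept, drop = FALSE], sim$Gamma, sim$se_Gamma)
    write_mrpipe_tsv(as_tibble(fit), file.path(out_dir, "mvmr.tsv"), seed)
    results$mvmr <- fit
    note("mvmr", "ok", nrow(fit))
  } else note("mvmr", "skipped", 0L)

  # --- two-step mediation ---------------------------------------------
  if (!is.null(config$mediation)) {
    cfg <- sim_config(seed = seed + 500L,
                      n_proteins = config$mediation$n_proteins,
                      n_mediators = config$mediation$n_mediators)
    sim <- simulate_proteome_and_weights(cfg)
    med <- two_step_mediation(sim$step1, sim$step2, fdr_threshold = th$fdr)
    write_mrpipe_tsv(med, file.path(out_dir, "mediation.tsv"), seed)
    results$mediation <- med
    results$proteome_sim <- sim
    note("mediation", "ok", nrow(med))
  } else note("mediation", "skipped", 0L)

  # --- colocalization --------------------------------------------------
  if (!is.null(config$coloc)) {
    cfg <- sim_config(seed = seed + 600L,
                      causal_config = config$coloc$causal_config)
    sim <- simulate_coloc_region(cfg)
    cres <- coloc_abf(sim$trait1, sim$trait2)
    crow <- dplyr::bind_cols(glance(cres),
                             tibble(!!!as.list(cres$pp)))
    write_mrpipe_tsv(crow, file.path(out_dir, "coloc.tsv"), seed)
    results$coloc <- cres
    note("coloc", "ok", 1L)
  } else note("coloc", "skipped", 0L)

  # --- TWAS overlap -----------------------------------------------------
  if (!is.null(config$twas)) {
    sim <- results$proteome_sim
    if (is.null(sim)) {
      cfg <- sim_config(seed = seed + 500L)
      sim <- simulate_proteome_and_weights(cfg)
    }
    disease_twas <- purrr::map_dfr(sim$weights, twas_association,
                                   gwas_z = sim$disease_z, ld = sim$ld,
                                   trait = "disease")
    poll_twas <- purrr::map_dfr(sim$weights, twas_association,
                                gwas_z = sim$pollutant_z, ld = sim$ld,
                                trait = "pollutant")
    overlap <- concordant_overlap_and_rank(
      disease_twas, list(pollutant = poll_twas), alpha = th$alpha)
    write_mrpipe_tsv(overlap, file.path(out_dir, "twas_overlap.tsv"), seed)
    results$twas <- overlap
    note("twas", "ok", nrow(overlap))
  } else note("twas", "skipped", 0L)

  run_log <- dplyr::bind_rows(log_rows)
  run_log$version <- as.character(utils::packageVersion("mrpipe"))
  run_log$seed <- seed
  run_log$thresholds <- paste(names(th), unlist(th), sep = "=",
                              collapse = ";")
  write_mrpipe_tsv(run_log, file.path(out_dir, "run_log.tsv"), seed)
  results$run_log <- run_log
  invisible(results)
}
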