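make_ld <- function(ids, r = NULL) {
  m <- r %||% diag(length(ids))
  dimnames(m) <- list(ids, ids)
  m
}

test_that("TWAS statistic combines z-scores through LD as w'z / sqrt(w'Rw)", {
  z <- tibble::tibble(variant_id = c("rs1", "rs2"), z = c(2, 2))
  ld <- make_ld(c("rs1", "rs2"))

  single <- twas_association(tibble::tibble(variant_id = "rs1", weight = 1),
                             z, ld)
  expect_equal(single$z_twas, 2)

  both <- twas_association(tibble::tibble(variant_id = c("rs1", "rs2"),
                                          weight = c(1, 1)), z, ld)
  expect_equal(both$z_twas, 4 / sqrt(2), tolerance = 1e-12)

  cancel <- twas_association(tibble::tibble(variant_id = c("rs1", "rs2"),
                                            weight = c(1, -1)), z, ld)
  expect_equal(cancel$z_twas, 0)
})

test_that("TWAS statistic is scale-invariant in w and antisymmetric under negation", {
  withr::with_seed(3, {
    ids <- sprintf("rs%d", 1:6)
    R <- random_corr(6, seed = 31)
    dimnames(R) <- list(ids, ids)
    z <- tibble::tibble(variant_id = ids, z = rnorm(6))
    w <- tibble::tibble(variant_id = ids, weight = rnorm(6))
    base <- twas_association(w, z, R)$z_twas
    w2 <- w; w2$weight <- w2$weight * 7.3
    expect_equal(twas_association(w2, z, R)$z_twas, base, tolerance = 1e-12)
    w3 <- w; w3$weight <- -w3$weight
    expect_equal(twas_association(w3, z, R)$z_twas, -base, tolerance = 1e-12)
  })
})

test_that("Fisher's combination matches chi-square tails including printed cases", {
  # a single p passes through unchanged
  expect_equal(fisher_combined(0.037), 0.037, tolerance = 1e-12)
  expect_equal(fisher_combined(c(1, 1)), 1)

  # closed-form 4-df tail: p = (1 + X/2) exp(-X/2)
  x <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(fisher_combined(c(0.05, 0.05)), (1 + x / 2) * exp(-x / 2),
               tolerance = 1e-12)
  expect_equal(fisher_combined(c(0.05, 0.05)), 0.0174787, tolerance = 1e-5)

  # published worked examples; the second row's inputs are printed to
  # 3 s.f., which already moves the combination by ~0.2%
  expect_equal(signif(fisher_combined(c(3.35e-5, 2.82e-2)), 3), 1.40e-5)
  expect_lt(abs(fisher_combined(c(1.78e-2, 3.80e-4)) - 8.75e-5) / 8.75e-5,
            0.01)

  expect_error(fisher_combined(c(0.05, 0)), "floor")
})

test_that("Fisher's combination is exchangeable and monotone", {
  p <- c(0.01, 0.3, 0.07)
  expect_equal(fisher_combined(p), fisher_combined(rev(p)), tolerance = 1e-15)
  expect_lt(fisher_combined(c(0.005, 0.3, 0.07)), fisher_combined(p))
})

test_that("the 8-df pairwise-FCP composition reproduces published FCP.All values", {
  bend3 <- c(1.40e-5, 7.25e-6, 1.09e-5, 5.22e-6)
  expect_equal(signif(fisher_combined(bend3), 3), 1.04e-16)
  slc35a1 <- c(7.43e-3, 3.77e-3, 2.41e-3, 8.22e-5)
  expect_equal(signif(fisher_combined(slc35a1), 3), 1.81e-8)
})

test_that("overlap requires concordant significant pairs and ranks by FCP", {
  disease <- tibble::tibble(gene = c("G1", "G2", "G3"),
                            z_twas = c(4, 3, -3),
                            pval = c(1e-4, 3e-3, 3e-3))
  poll <- list(
    no2 = tibble::tibble(gene = c("G1", "G2", "G3"),
                         z_twas = c(2.5, -2.5, -2.2),
                         pval = c(1.2e-2, 1.2e-2, 2.8e-2))
  )
  out <- concordant_overlap_and_rank(disease, poll)
  # G2 has discordant signs; G1 and G3 are concordant and significant
  expect_setequal(out$gene, c("G1", "G3"))
  expect_equal(out$rank_pair[out$gene == "G1"], 1L)
  expect_equal(out$rank_pair[out$gene == "G3"], 2L)
  expect_equal(out$fcp_pair[out$gene == "G1"],
               fisher_combined(c(1e-4, 1.2e-2)), tolerance = 1e-12)
  # single pollutant: fcp_all is the 2-df combination of one pairwise FCP
  expect_equal(out$fcp_all[out$gene == "G1"],
               out$fcp_pair[out$gene == "G1"], tolerance = 1e-12)
})

test_that("a gene must overlap every pollutant to receive FCP.All", {
  disease <- tibble::tibble(gene = c("G1", "G2"), z_twas = c(4, 4),
                            pval = c(1e-4, 1e-4))
  poll <- list(
    a = tibble::tibble(gene = c("G1", "G2"), z_twas = c(3, 3),
                       pval = c(1e-3, 1e-3)),
    b = tibble::tibble(gene = c("G1", "G2"), z_twas = c(3, 3),
                       pval = c(1e-3, 0.5))
  )
  out <- concordant_overlap_and_rank(disease, poll)
  expect_true(all(is.na(out$fcp_all[out$gene == "G2"])))
  expect_false(any(is.na(out$fcp_all[out$gene == "G1"])))
})

test_that("published TWAS row composes from raw p-values to pairwise FCPs and FCP.All", {
  disease_p <- 3.35e-5
  poll_p <- c(no2 = 2.82e-2, nox = 1.39e-2, pm25 = 2.15e-2, pm10 = 9.78e-3)
  disease <- tibble::tibble(gene = "BEND3", z_twas = 4.15, pval = disease_p)
  poll <- purrr::imap(poll_p, function(p, nm) {
    tibble::tibble(gene = "BEND3", z_twas = 2.3, pval = unname(p))
  })
  out <- concordant_overlap_and_rank(disease, poll)
  expect_equal(signif(out$fcp_pair[out$pollutant == "no2"], 3), 1.40e-5)
  expect_equal(signif(out$fcp_pair[out$pollutant == "nox"], 3), 7.25e-6)
  expect_equal(signif(out$fcp_pair[out$pollutant == "pm25"], 3), 1.09e-5)
  expect_equal(signif(out$fcp_pair[out$pollutant == "pm10"], 3), 5.22e-6)
  expect_equal(signif(out$fcp_all[1], 3), 1.04e-16)
})

test_that("planted TWAS genes surface in the overlap and null genes mostly do not", {
  hits <- 0; false_hits <- 0; n_seeds <- 25
  for (s in 1:n_seeds) {
    sim <- simulate_proteome_and_weights(sim_config(seed = 7000 + s))
    disease <- purrr::map_dfr(sim$weights, twas_association,
                              gwas_z = sim$disease_z, ld = sim$ld,
                              trait = "disease")
    poll <- purrr::map_dfr(sim$weights, twas_association,
                           gwas_z = sim$pollutant_z, ld = sim$ld,
                           trait = "pollutant")
    out <- concordant_overlap_and_rank(disease, list(p = poll))
    planted <- sim$truth$planted_proteins
    if (all(planted %in% out$gene)) hits <- hits + 1
    null_genes <- setdiff(disease$gene, planted)
    false_hits <- false_hits + sum(null_genes %in% out$gene) /
      length(null_genes)
  }
  expect_gte(hits / n_seeds, 0.85)
  expect_lte(false_hits / n_seeds, 0.10)
})
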