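test_that("fixed-effects pooling matches hand arithmetic and the scaling law", {
  m <- meta_fixed(tibble::tibble(beta = c(0.3, 0.3), se = c(0.1, 0.1)))
  expect_equal(m$pooled_beta, 0.3)
  expect_equal(m$pooled_se, sqrt(1 / 200), tolerance = 1e-12)
  expect_equal(m$het_q, 0)

  m <- meta_fixed(tibble::tibble(beta = c(0.2, 0.4), se = c(0.1, 0.2)))
  expect_equal(m$pooled_beta, (100 * 0.2 + 25 * 0.4) / 125, tolerance = 1e-12)
  expect_equal(m$pooled_se, 125^-0.5, tolerance = 1e-12)

  # n identical estimates (b, s) pool to (b, s/sqrt(n))
  m <- meta_fixed(tibble::tibble(beta = rep(0.15, 5), se = rep(0.2, 5)))
  expect_equal(m$pooled_beta, 0.15)
  expect_equal(m$pooled_se, 0.2 / sqrt(5))

  expect_warning(meta_fixed(tibble::tibble(beta = 0.1, se = 0.1)), "single")
})

test_that("fixed-effects pooling stays within input range and below min input SE", {
  withr::with_seed(8, {
    for (i in 1:10) {
      est <- tibble::tibble(beta = rnorm(4), se = runif(4, 0.05, 0.3))
      m <- meta_fixed(est)
      expect_gte(m$pooled_beta, min(est$beta))
      expect_lte(m$pooled_beta, max(est$beta))
      expect_lte(m$pooled_se, min(est$se) + 1e-12)
    }
  })
})

test_that("fixed-effects pooling agrees with metafor", {
  est <- tibble::tibble(beta = c(0.31, 0.22, 0.40), se = c(0.10, 0.07, 0.15))
  m <- meta_fixed(est)
  ref <- metafor::rma(yi = est$beta, sei = est$se, method = "FE")
  expect_equal(m$pooled_beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(m$pooled_se, ref$se, tolerance = 1e-10)
  expect_equal(m$het_q, as.numeric(ref$QE), tolerance = 1e-10)
})

test_that("MVMR with orthogonal instruments reproduces univariable IVW", {
  # exactly block-diagonal design: the normal equations decouple and each
  # direct effect equals the univariable IVW on its own block
  sim <- simulate_mvmr(sim_config(seed = 31, cross_loading = 0))
  design0 <- sim$design
  bs <- 30
  design0[1:bs, 2] <- 0
  design0[(bs + 1):(2 * bs), 1] <- 0
  fit <- mvmr_fit(design0, sim$Gamma, sim$se_Gamma)
  for (e in 1:2) {
    block <- ((e - 1) * bs + 1):(e * bs)
    pair <- make_pair(design0[block, e], sim$Gamma[block],
                      se_Gamma = sim$se_Gamma[block])
    uni <- mr_ivw(pair)
    expect_equal(fit$direct_beta[e], uni$beta, tolerance = 1e-10)
  }
})

test_that("MVMR interval estimates cover the planted direct effects", {
  covered <- 0; n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    sim <- simulate_mvmr(sim_config(seed = 1500 + s))
    fit <- mvmr_fit(sim$design, sim$Gamma, sim$se_Gamma)
    truth <- sim$truth$direct_betas
    if (all(abs(fit$direct_beta - truth) < qnorm(0.975) * fit$se)) {
      covered <- covered + 1
    }
  }
  # joint coverage of two ~95% intervals
  expect_gte(covered / n_seeds, 0.80)
})

test_that("MVMR estimates match the normal-equations oracle and permute cleanly", {
  withr::with_seed(12, {
    k <- 10
    X <- cbind(a = rnorm(k, 0.1, 0.03), b = rnorm(k, -0.05, 0.03))
    seG <- runif(k, 0.05, 0.15)
    G <- X %*% c(0.3, -0.2) + rnorm(k, 0, 0.02)
    fit <- mvmr_fit(X, drop(G), seG)
    w <- 1 / seG^2
    oracle <- solve(t(X) %*% (w * X), t(X) %*% (w * G))
    expect_equal(fit$direct_beta, drop(oracle), tolerance = 1e-10,
                 ignore_attr = TRUE)

    perm <- mvmr_fit(X[, c("b", "a")], drop(G), seG)
    expect_equal(perm$direct_beta[perm$exposure == "a"],
                 fit$direct_beta[fit$exposure == "a"], tolerance = 1e-12)
  })
})

test_that("MVMR degenerate designs raise the documented errors", {
  X <- cbind(a = c(0.1, 0.2, 0.3), b = c(0.2, 0.4, 0.6))  # collinear
  expect_error(mvmr_fit(X, c(0.1, 0.2, 0.3), rep(0.1, 3)),
               class = "mrpipe_collinearity_error")
  X2 <- cbind(a = c(0.1, 0.2), b = c(0.05, 0.3))
  expect_error(mvmr_fit(X2, c(0.1, 0.2), rep(0.1, 2)), "underdetermined")
})

test_that("end-to-end mvmr_ivw on simulated tables recovers direct effects", {
  sim <- simulate_mvmr(sim_config(seed = 77))
  fit <- mvmr_ivw(sim$exposures, sim$outcome, sim$ld)
  truth <- sim$truth$direct_betas
  expect_equal(sort(fit$exposure), sort(names(truth)))
  m <- match(fit$exposure, names(truth))
  expect_true(all(abs(fit$direct_beta - truth[m]) < 2.5 * fit$se))
  expect_gt(attr(fit, "n_snp"), length(truth))
})

test_that("lasso selection drops duplicates and noise but keeps signal", {
  sim <- simulate_mvmr(sim_config(seed = 41, duplicate_exposure = TRUE))
  kept <- lasso_select_exposures(sim$design, sim$Gamma,
                                 weights = 1 / sim$se_Gamma^2, seed = 5)
  # perfectly collinear duplicate: only one of the pair retained
  expect_false(all(c("exposure_1", "exposure_dup") %in% kept))
  expect_true(length(kept) >= 1)

  # strong independent signals are retained across seeds
  n_keep <- 0
  for (s in 1:20) {
    sim <- simulate_mvmr(sim_config(seed = 500 + s))
    kept <- lasso_select_exposures(sim$design, sim$Gamma,
                                   weights = 1 / sim$se_Gamma^2, seed = s)
    if (all(c("exposure_1", "exposure_2") %in% kept)) n_keep <- n_keep + 1
  }
  expect_gte(n_keep, 19)

  # a pure-noise column is excluded most of the time
  n_drop <- 0
  for (s in 1:20) {
    withr::with_seed(600 + s, {
      k <- 100
      X <- cbind(signal = rnorm(k, 0, 0.05), noise = rnorm(k, 0, 0.05))
      G <- 0.4 * X[, 1] + rnorm(k, 0, 0.01)
      kept <- lasso_select_exposures(X, G, seed = s)
      if (!("noise" %in% kept)) n_drop <- n_drop + 1
    })
  }
  expect_gte(n_drop, 16)
})

test_that("total-versus-direct gap uses the independence SE", {
  gap <- total_vs_direct(0.5, 0.1, 0.3, 0.1, "bmi")
  expect_equal(gap$gap, 0.2)
  expect_equal(gap$gap_se, sqrt(0.02), tolerance = 1e-12)
  expect_equal(total_vs_direct(0.4, 0.1, 0.4, 0.1, "x")$gap, 0)

  # generator with a mediator carrying 40% of the total effect:
  # direct 0.3, mediated 0.4 * 0.5 = 0.2, so total 0.5 and gap/total 0.4
  gaps <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      k <- 60
      g <- rnorm(k, 0.1, 0.03)
      u <- rnorm(k, 0, 0.05)
      m <- 0.5 * g + u                    # exposure -> mediator path
      G <- 0.3 * g + 0.4 * m + rnorm(k, 0, 0.02)
      seG <- rep(0.02, k)
      tot <- mr_ivw(make_pair(g, G, se_Gamma = seG))
      dir <- mvmr_fit(cbind(expo = g, med = m), G, seG)
      (tot$beta - dir$direct_beta[1]) / tot$beta
    })
  }, numeric(1))
  expect_equal(mean(gaps), 0.4, tolerance = 0.1)
})
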