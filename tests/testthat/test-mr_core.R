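test_that("Wald ratio follows the first-order formulas", {
  expect_equal(mr_wald_ratio(0.1, 0.01, 0.05, 0.02)$beta, 0.5)
  expect_equal(mr_wald_ratio(0.2, 0.01, 0, 0.02)$beta, 0)
  wr <- mr_wald_ratio(-0.3, 0.01, 0.06, 0.02)
  expect_equal(wr$beta, -0.2)
  expect_equal(wr$se, 0.02 / 0.3)
  expect_error(mr_wald_ratio(0, 0.01, 0.1, 0.02), "undefined")
})

test_that("IVW matches closed-form weighted least squares through the origin", {
  # exact proportionality: slope recovered, Q = 0, RE does not inflate
  pair <- make_pair(gamma = c(1, 2), Gamma = c(0.3, 0.6),
                    se_Gamma = c(0.2, 0.5))
  fit <- mr_ivw(pair)
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$q_stat, 0, tolerance = 1e-12)
  w <- 1 / c(0.2, 0.5)^2
  expect_equal(fit$se, sum(w * c(1, 2)^2)^-0.5)

  # hand-computed two-SNP case with heterogeneity
  pair <- make_pair(gamma = c(1, 1), Gamma = c(0.4, 0.6),
                    se_Gamma = c(0.1, 0.1))
  fit <- mr_ivw(pair)
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$q_stat, 2)
  expect_equal(fit$q_df, 1L)
  expect_equal(fit$se, sqrt(1 / 200) * sqrt(2), tolerance = 1e-12)
  expect_equal(fit$or, exp(0.5))
  expect_true(fit$ci_low <= fit$or && fit$or <= fit$ci_high)

  # with equal outcome SEs and proportional data IVW is OLS through origin
  g <- c(0.5, 1, 2, 3); G <- 0.7 * g
  fit <- mr_ivw(make_pair(g, G, se_Gamma = rep(0.3, 4)))
  expect_equal(fit$beta, sum(g * G) / sum(g^2), tolerance = 1e-12)
})

test_that("IVW and Egger agree with an independent normal-equations oracle", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      k <- 10
      g <- rnorm(k, 0.1, 0.05)
      G <- 0.4 * g + rnorm(k, 0, 0.02)
      seG <- runif(k, 0.05, 0.2)
      pair <- make_pair(g, G, se_Gamma = seG)
      w <- 1 / seG^2

      ivw <- mr_ivw(pair)
      expect_equal(ivw$beta, sum(w * g * G) / sum(w * g^2), tolerance = 1e-10)

      egger <- mr_egger(pair)
      # oracle: solve the weighted normal equations after gamma-orientation
      s <- ifelse(g < 0, -1, 1)
      X <- cbind(1, g * s)
      b <- solve(t(X) %*% (w * X), t(X) %*% (w * (G * s)))
      expect_equal(egger$egger_intercept, b[1], tolerance = 1e-10)
      expect_equal(egger$beta, b[2], tolerance = 1e-10)
    })
  }
})

test_that("Egger recovers exact affine data with zero heterogeneity", {
  g <- c(0.1, 0.2, 0.3, 0.4)
  G <- 0.1 + 0.3 * g
  fit <- mr_egger(make_pair(g, G, se_Gamma = rep(0.1, 4)))
  expect_equal(fit$egger_intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$q_stat, 0, tolerance = 1e-20)
  expect_equal(fit$q_df, 2L)
  expect_error(mr_egger(make_pair(c(1, 2), c(1, 2))), "at least 3")
})

test_that("estimators are scale-equivariant and orientation behaves as designed", {
  pair <- make_pair(gamma = c(0.1, 0.25, 0.4, -0.2),
                    Gamma = c(0.05, 0.1, 0.11, -0.07),
                    se_Gamma = c(0.1, 0.12, 0.09, 0.11))
  c0 <- 2.5
  scaled <- make_pair(pair$gamma * c0, pair$Gamma, se_Gamma = pair$se_Gamma)
  expect_equal(mr_ivw(scaled)$beta, mr_ivw(pair)$beta / c0, tolerance = 1e-12)
  expect_equal(mr_egger(scaled)$beta, mr_egger(pair)$beta / c0,
               tolerance = 1e-12)

  # IVW and weighted median are invariant to per-variant sign flips
  flip <- c(1, -1, 1, -1)
  flipped <- make_pair(pair$gamma * flip, pair$Gamma * flip,
                       se_Gamma = pair$se_Gamma)
  expect_equal(mr_ivw(flipped)$beta, mr_ivw(pair)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(flipped, seed = 9, n_boot = 50)$beta,
               mr_weighted_median(pair, seed = 9, n_boot = 50)$beta,
               tolerance = 1e-12)
})

test_that("weighted median interpolates the defining percentile formula", {
  # symmetric case: plain median
  pair <- make_pair(gamma = c(1, 1, 1), Gamma = c(0.2, 0.5, 0.8))
  fit <- mr_weighted_median(pair, seed = 1, n_boot = 100)
  expect_equal(fit$beta, 0.5)

  # identical ratios: estimate equals them, bootstrap SE small
  pair <- make_pair(gamma = c(1, 2, 3), Gamma = c(0.4, 0.8, 1.2),
                    se_Gamma = c(0.01, 0.01, 0.01))
  fit <- mr_weighted_median(pair, seed = 1, n_boot = 100)
  expect_equal(fit$beta, 0.4, tolerance = 1e-12)
  expect_lt(fit$se, 0.05)

  # step-through oracle for ratios (.1,.2,.3,1) with weights (.1,.2,.3,.4):
  # percentiles p_j = S_j - w_j/2 = (.05,.2,.45,.8); interpolating 0.5
  # between (0.45, 0.3) and (0.8, 1.0) gives 0.3 + (0.05/0.35)*0.7 = 0.4
  b <- c(0.1, 0.2, 0.3, 1.0)
  w <- c(0.1, 0.2, 0.3, 0.4)
  gamma <- sqrt(w)               # weights w_j = gamma^2/se_Gamma^2 with se 1
  pair <- make_pair(gamma, b * gamma, se_Gamma = rep(1, 4))
  fit <- mr_weighted_median(pair, seed = 1, n_boot = 50)
  expect_equal(fit$beta, 0.4, tolerance = 1e-12)

  expect_error(mr_weighted_median(pair), "seed")
})

test_that("heterogeneity Q is zero iff all Wald ratios coincide", {
  pair <- make_pair(gamma = c(1, 2, 4), Gamma = c(0.25, 0.5, 1))
  expect_lt(mr_ivw(pair)$q_stat, 1e-12)
  pair2 <- make_pair(gamma = c(1, 2, 4), Gamma = c(0.25, 0.5, 1.4))
  expect_gt(mr_ivw(pair2)$q_stat, 1e-6)
})

test_that("leave-one-out flags the planted outlier and keeps row count", {
  g <- rep(0.1, 6)
  G <- 0.03 * g / 0.1
  G[6] <- 10 * G[6]               # one ratio 10x the rest
  pair <- make_pair(g, G, se_Gamma = rep(0.05, 6))
  loo <- leave_one_out(pair)
  expect_equal(nrow(loo), 6)
  shift <- abs(loo$beta - attr(loo, "full_fit")$beta)
  expect_equal(which.max(shift), 6)

  # perfectly proportional data: all rows equal the full estimate
  pair <- make_pair(c(1, 2, 3), c(0.3, 0.6, 0.9))
  loo <- leave_one_out(pair)
  expect_equal(loo$beta, rep(0.3, 3), tolerance = 1e-12)
  expect_false(attr(loo, "flag_sign_flip"))
  expect_equal(nrow(leave_one_out(make_pair(1:3, c(1, 2, 3.5)))), 3)
})

test_that("BH tiers reproduce step-up arithmetic including hand case", {
  res <- bh_fdr(c(0.001, 0.01, 0.02, 0.04))
  expect_equal(res$fdr_q, c(0.004, 0.02, 4 * 0.02 / 3, 0.04),
               tolerance = 1e-12)

  res <- bh_fdr(rep(0.05, 6))
  expect_equal(res$fdr_q, rep(0.05, 6))

  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")

  # tier rule: q < .05 significant; p < .05 <= q suggestive; else null
  res <- bh_fdr(c(1e-4, 0.04, 0.5), tiers = TRUE)
  expect_equal(res$tier[1], "significant")
  expect_equal(res$tier[3], "null")
})

test_that("binary-outcome power behaves at the null, the limit, and in between", {
  expect_equal(mr_power_binary(1e5, 0.1, 0.003, or_hypothesized = 1),
               pnorm(-qnorm(0.975)), tolerance = 1e-12)
  expect_gt(mr_power_binary(1e6, 0.5, 0.5, or_hypothesized = 3), 0.999999)
  expect_warning(mr_power_binary(1e5, 0.1, 0, 1.5), "alpha")
  p <- mr_power_binary(3e5, 0.05, 0.003, 1.37)
  expect_true(p > 0 && p < 1)
})

test_that("power approximation agrees with a Monte-Carlo oracle of the estimator", {
  # simulate the IVW estimator's sampling distribution at the design point
  n <- 3e5; K <- 0.05; r2 <- 0.003; or <- 1.37
  analytic <- mr_power_binary(n, K, r2, or)
  mc <- withr::with_seed(99, {
    se_hat <- 1 / sqrt(n * r2 * K * (1 - K))
    bhat <- rnorm(2000, log(or), se_hat)
    mean(abs(bhat / se_hat) > qnorm(0.975))
  })
  mc_se <- sqrt(mc * (1 - mc) / 2000)
  expect_lt(abs(analytic - mc), 3 * mc_se + 0.01)
})
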