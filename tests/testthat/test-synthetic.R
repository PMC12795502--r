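# Stationary cavity sampler and the Euler-Maruyama dgLV simulator.

test_that("non-interacting cohorts reproduce the single-species moments", {
  theta <- model_parameters(mu = 0, sigma = 0, T = 2e-3, lam = 2e-4)
  tab <- sample_cohort_stationary(theta, K = 0.05, S = 100, R = 60,
                                  compositional = FALSE, seed = 17)
  draws <- as.vector(tab$abundances)
  tm <- truncated_moments(1, 0.05, beta = 500, nu = 0.1, k_max = 2)
  m1 <- tm$moment[tm$k == 1]; m2 <- tm$moment[tm$k == 2]
  se1 <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m1), 3 * se1)
  se2 <- stats::sd(draws^2) / sqrt(length(draws))
  expect_lt(abs(mean(draws^2) - m2), 3 * se2)
})

test_that("closure, subsampling and the nu floor behave as specified", {
  theta <- theta_mid()
  tab <- sample_cohort_stationary(theta, K = 0.05, S = 40, R = 15, seed = 2)
  expect_equal(colSums(tab$abundances), rep(1, 15), ignore_attr = TRUE)
  expect_true(all(tab$abundances > 0))     # no zeros without subsampling

  sub <- sample_cohort_stationary(theta, K = 0.05, S = 40, R = 15, seed = 2,
                                  subsample_depth = 500)
  expect_true(all(sub$abundances >= 0))
  expect_gt(sum(sub$abundances == 0), 0)   # subsampling creates zeros
  expect_equal(colSums(sub$abundances), rep(1, 15), ignore_attr = TRUE)

  expect_error(
    sample_cohort_stationary(model_parameters(1, 0.3, 5e-3, 1e-5),
                             K = 0.05, S = 10, R = 2),
    "dominates the sampling")

  t1 <- sample_cohort_stationary(theta, K = 0.05, S = 20, R = 5, seed = 9)
  t2 <- sample_cohort_stationary(theta, K = 0.05, S = 20, R = 5, seed = 9)
  expect_identical(t1$abundances, t2$abundances)
})

test_that("generator round trip: empirical estimates match the fixed point", {
  theta <- theta_mid()                    # nu = 0.1 regime
  fp <- solve_self_consistency(theta, K = 0.05)
  tab <- sample_cohort_stationary(theta, K = 0.05, S = 100, R = 200,
                                  compositional = FALSE, seed = 31)
  A <- tab$abundances
  est <- estimate_order_parameters(tab)

  means_a <- colMeans(A)
  sq_a <- colMeans(A^2)
  se_h <- stats::sd(means_a) / sqrt(ncol(A))
  se_qd <- stats::sd(sq_a) / sqrt(ncol(A))
  se_q0 <- stats::sd(means_a^2) / sqrt(ncol(A))
  expect_lt(abs(est$h - fp$h), 3 * se_h)
  expect_lt(abs(est$q_d - fp$q_d), 3 * se_qd)
  expect_lt(abs(est$q_0 - fp$q_0), 3 * se_q0)
})

test_that("generator accuracy improves with cohort size", {
  theta <- theta_mid()
  fp <- solve_self_consistency(theta, K = 0.05)
  err_h <- vapply(c(20L, 180L), function(R) {
    tab <- sample_cohort_stationary(theta, K = 0.05, S = 60, R = R,
                                    compositional = FALSE, seed = 77)
    abs(estimate_order_parameters(tab)$h - fp$h)
  }, numeric(1))
  # 9x the samples: expect a clear reduction (rate ~ 1/sqrt(R S))
  expect_lt(err_h[2], err_h[1])
})

test_that("deterministic SDE limit relaxes monotonically to K", {
  out <- simulate_dglv_sde(list(mu = 0, sigma = 0, T = 0, lam = 0),
                           K = 1, S = 1, dt = 5e-3, t_burnin = 1,
                           t_total = 60, N0 = 0.2, seed = 1)
  tr <- out$mean_trace$mean_abundance
  expect_true(all(diff(tr) >= -1e-12))     # monotone logistic approach
  expect_equal(tr[length(tr)], 1, tolerance = 1e-6)
})

test_that("single-species stationary law matches the Ito stationary density", {
  # sigma = 0, T > 0, lambda > 0: p(N) ~ N^(beta lam - 1) exp(-beta(N^2/2 - K N))
  theta <- list(mu = 0, sigma = 0, T = 0.1, lam = 0.05)   # nu = 0.5
  out <- simulate_dglv_sde(theta, K = 1, S = 1, dt = 5e-3, t_burnin = 100,
                           t_total = 3000, seed = 4)
  snaps <- as.vector(out$table$abundances)
  tm <- truncated_moments(1, 1, beta = 10, nu = 0.5, k_max = 2)
  m1 <- tm$moment[tm$k == 1]; m2 <- tm$moment[tm$k == 2]
  n_eff <- length(snaps)                   # snapshots are decorrelated
  se1 <- stats::sd(snaps) / sqrt(n_eff)
  se2 <- stats::sd(snaps^2) / sqrt(n_eff)
  expect_lt(abs(mean(snaps) - m1), 3 * se1 + 0.01 * m1)   # 3 SE + O(dt) bias
  expect_lt(abs(mean(snaps^2) - m2), 3 * se2 + 0.02 * m2)
})

test_that("weak-disorder community dynamics agree with the RS fixed point", {
  theta <- list(mu = 1, sigma = 0.1, T = 5e-3, lam = 5e-4)
  K <- 0.5; S <- 100
  fp <- solve_self_consistency(model_parameters(1, 0.1, 5e-3, 5e-4), K = K)
  out <- simulate_dglv_sde(theta, K = K, S = S, dt = 5e-3, t_burnin = 100,
                           t_total = 400, seed = 6)
  A <- out$table$abundances
  expect_lt(abs(mean(A) - fp$h) / fp$h, 0.1)
  expect_lt(abs(mean(A^2) - fp$q_d) / fp$q_d, 0.1)
})

test_that("trajectories flagged as divergent raise an error", {
  # mu = -2 (strong mutual facilitation): unbounded growth
  expect_error(
    simulate_dglv_sde(list(mu = -2, sigma = 0, T = 0, lam = 0), K = 1,
                      S = 20, dt = 5e-3, t_burnin = 1, t_total = 50,
                      N0 = 1, seed = 2),
    "unbounded growth")
})

test_that("recovery experiment is reproducible end to end", {
  theta <- theta_mid()
  r1 <- parameter_recovery_experiment(theta, K = 0.05, S = 40, R = 30,
                                      n_restarts = 4, seed = 3)
  r2 <- parameter_recovery_experiment(theta, K = 0.05, S = 40, R = 30,
                                      n_restarts = 4, seed = 3)
  expect_identical(r1$errors, r2$errors)
  expect_identical(tidy(r1$fit), tidy(r2$fit))
})
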