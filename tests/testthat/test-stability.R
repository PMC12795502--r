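# Replicon eigenvalue, RSB distance, niche-neutral ratio, interaction summary.

test_that("replicon vanishes without disorder and respects its upper bound", {
  pi <- pi_mid()
  expect_equal(replicon(model_parameters(1, 0, 2e-3, 2e-4), pi), 0)
  theta <- theta_mid()
  r <- replicon(theta, pi)
  expect_lte(r, (theta$beta * theta$sigma)^2)
})

test_that("the two printed forms of the replicon agree (response vs variance)", {
  theta <- theta_weak()
  pi <- solve_self_consistency(theta, K = 0.05)
  r_var <- replicon(theta, pi)

  # response form: (dE[N]/dzeta)^2 / beta^2 replaces Var^2, averaged over z
  gh <- pracma::gaussHermite(101)
  z <- sqrt(2) * gh$x; w <- gh$w / sqrt(pi)
  m <- as.numeric(mass(theta, pi))
  zeta <- pi$K - theta$mu * pi$h + sqrt(pi$q_0) * theta$sigma * z
  dz <- 1e-5
  m1 <- function(zv) {
    vapply(zv, function(zz) {
      tm <- truncated_moments(m, zz, theta$beta, theta$nu, k_max = 1)
      tm$moment[tm$k == 1]
    }, numeric(1))
  }
  resp <- (m1(zeta + dz) - m1(zeta - dz)) / (2 * dz)
  mean_resp_sq <- sum(w * (resp / theta$beta)^2)
  bs2 <- (theta$beta * theta$sigma)^2
  r_resp <- bs2 * (1 - bs2 * mean_resp_sq)
  expect_equal(r_var, r_resp, tolerance = 1e-4)
})

test_that("replicon matches the dense double-quadrature oracle", {
  theta <- model_parameters(0.8, 0.45, 3e-3, 1e-4)
  pi <- list(h = 0.015, q_d = 9e-4, q_0 = 2.4e-4, K = 0.06)
  r <- replicon(theta, pi, nodes = 151)
  bs2 <- (theta$beta * theta$sigma)^2
  ref <- bs2 * (1 - bs2 * oracle_mean_var_sq(theta, pi))
  expect_equal(r, ref, tolerance = 1e-6)
})

test_that("critical sigma is a true root, matches a grid scan, and is unique", {
  theta <- theta_mid()
  pi <- solve_self_consistency(theta, K = 0.05)
  cs <- critical_sigma(theta, pi)
  expect_true(cs$crossing_found)
  bs2 <- (theta$beta * cs$sigma_c)^2
  expect_lte(abs(cs$residual), 1e-5 * bs2)
  expect_equal(cs$distance, cs$sigma_c - theta$sigma)

  # grid oracle: |replicon| minimized at the bisection root within spacing
  sig_grid <- seq(max(cs$sigma_c - 0.05, 1e-3), cs$sigma_c + 0.05,
                  length.out = 41)
  rg <- vapply(sig_grid, function(s) {
    replicon(model_parameters(theta$mu, s, theta$T, theta$lam), pi)
  }, numeric(1))
  expect_lt(abs(sig_grid[which.min(abs(rg))] - cs$sigma_c),
            2 * diff(sig_grid[1:2]))
  # locally decreasing through the root -> unique in the bracket
  expect_true(all(diff(rg) < 0))
})

test_that("niche-neutral ratio obeys its limits and the mode-counting oracle", {
  # sigma_zeta -> 0: indicator of |zeta_bar| > zeta_star
  pi0 <- list(h = 0.02, q_d = 5e-4, q_0 = 4e-4, K = 0.05)
  th_small <- model_parameters(mu = 0, sigma = 0, T = 1e-3, lam = 1e-4)
  zs <- sqrt(4 * (1 - th_small$nu) * 1 / th_small$beta)
  expect_equal(niche_neutral_ratio(th_small, pi0),
               as.numeric(abs(pi0$K) > zs))

  # nu >= 1 is refused (modal regime)
  expect_error(niche_neutral_ratio(model_parameters(0, 0.1, 1e-3, 2e-3), pi0),
               "modal")

  # psi increases with sigma_zeta when zeta_bar < zeta_star
  th_base <- model_parameters(mu = 0, sigma = 0.5, T = 1e-3, lam = 1e-4)
  m0 <- as.numeric(mass(th_base, pi0))
  zs0 <- sqrt(4 * (1 - th_base$nu) * m0 / th_base$beta)
  stopifnot(pi0$K < zs0)
  psis <- vapply(seq(0.2, 3, length.out = 8), function(s) {
    niche_neutral_ratio(model_parameters(0, s, 1e-3, 1e-4),
                        list(h = pi0$h, q_d = pi0$q_d, q_0 = pi0$q_0,
                             K = pi0$K))
  }, numeric(1))
  expect_true(all(diff(psis) > 0))

  # Monte-Carlo oracle: fraction of disorder draws whose SAD has an interior
  # mode.  The stationary-point equation beta m N^2 - beta zeta N - (nu-1) = 0
  # has a positive maximum root iff zeta > zeta_star; the parameters are
  # chosen with zeta_bar > 0 and P(zeta < -zeta_star) negligible, where the
  # mode count and P(|zeta| > zeta_star) coincide.
  theta <- model_parameters(1, 0.6, 2e-3, 2e-4)
  pi <- solve_self_consistency(theta, K = 0.05)
  psi <- niche_neutral_ratio(theta, pi)
  m <- as.numeric(mass(theta, pi))
  zeta_star <- sqrt(4 * (1 - theta$nu) * m / theta$beta)
  zeta_bar <- pi$K - theta$mu * pi$h
  sigma_zeta <- sqrt(pi$q_0) * theta$sigma
  set.seed(99)
  n_mc <- 1e6
  zeta <- stats::rnorm(n_mc, zeta_bar, sigma_zeta)
  disc <- (theta$beta * zeta)^2 + 4 * theta$beta * m * (theta$nu - 1)
  has_root <- disc >= 0
  n_plus <- (theta$beta * zeta[has_root] +
               sqrt(disc[has_root])) / (2 * theta$beta * m)
  modal <- logical(n_mc)
  modal[has_root] <- n_plus > 0
  frac <- mean(modal)
  se <- sqrt(frac * (1 - frac) / n_mc)
  expect_lt(abs(frac - psi), 3 * max(se, 1e-6))
})

test_that("interaction summary has the right marginals and symmetry", {
  theta0 <- model_parameters(2, 0, 1e-3, 1e-4)
  is0 <- interaction_summary(theta0, S = 10, seed = 1)
  off <- is0$alpha[upper.tri(is0$alpha)]
  expect_true(all(off == 2 / 10))

  theta <- model_parameters(1, 0.8, 1e-3, 1e-4)
  is1 <- interaction_summary(theta, S = 500, seed = 2)
  expect_identical(is1$alpha, t(is1$alpha))
  expect_equal(is1$mu_alpha, 1 / 500)
  expect_equal(is1$sigma_alpha, 0.8 / sqrt(500))

  # sampling check: replicate means/SDs within 3 standard errors
  reps <- vapply(1:100, function(s) {
    a <- interaction_summary(theta, S = 100, seed = s)$alpha
    off <- a[upper.tri(a)]
    c(mean(off), stats::sd(off))
  }, numeric(2))
  n_off <- 100 * 99 / 2
  se_mean <- (0.8 / sqrt(100)) / sqrt(n_off * 100)
  expect_lt(abs(mean(reps[1, ]) - 1 / 100), 3 * se_mean)
  expect_lt(abs(mean(reps[2, ]) - 0.8 / sqrt(100)),
            3 * stats::sd(reps[2, ]) / sqrt(100))
  expect_error(interaction_summary(theta, S = 1), "at least 2")
})

test_that("the RSB line can also be reached in beta at fixed sigma", {
  theta <- theta_mid()
  pi <- solve_self_consistency(theta, K = 0.05)
  cb <- critical_sigma(theta, pi, root_in = "beta")
  expect_true(cb$crossing_found)
  expect_gt(cb$beta_c, theta$beta)   # lowering T moves toward the RSB line
})

test_that("stability metrics are pure functions of (theta, pi)", {
  theta <- theta_mid()
  pi <- solve_self_consistency(theta, K = 0.05)
  m1 <- stability_metrics(theta, pi, find_sigma_c = FALSE)
  m2 <- stability_metrics(theta, pi, find_sigma_c = FALSE)
  expect_identical(m1, m2)
  expect_true(m1$psi >= 0 && m1$psi <= 1)
})
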