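# Independent numerical oracles (adaptive QAGS via stats::integrate, with a
# u = t^s substitution for the singular head) and shared fixtures.  These
# deliberately avoid the package's quadrature machinery.

# E[t^k] for the standardized law t^(nu-1) exp(-t^2/2 + b t).
oracle_std_moment <- function(nu, b, k) {
  tp0 <- (b + sqrt(b^2 + 4 * nu)) / 2
  M <- nu * log(tp0) + b * tp0 - tp0^2 / 2   # common peak normalization
  Ik <- function(s) {
    tp <- (b + sqrt(b^2 + 4 * s)) / 2
    f <- function(t) exp((s - 1) * log(t) - t^2 / 2 + b * t - M)
    w <- min(1 / sqrt(max(1 + (s - 1) / tp^2, 1e-8)), 3)
    lo <- max(tp - 25 * w, 0); hi <- max(tp + 25 * w, 12)
    bulk <- stats::integrate(f, max(lo, 1), hi, rel.tol = 1e-12, abs.tol = 0)$value
    head <- 0
    if (lo < 1) {
      g <- function(u) {
        t <- u^(1 / s)
        exp(-t^2 / 2 + b * t - M) / s
      }
      head <- stats::integrate(g, 0, 1, rel.tol = 1e-12, abs.tol = 0)$value
    }
    head + bulk
  }
  Ik(nu + k) / Ik(nu)
}

# E[N^k] under p(N | zeta) in abundance units.
oracle_moment <- function(m, zeta, beta, nu, k) {
  scale <- sqrt(beta * m)
  oracle_std_moment(nu, zeta * beta / scale, k) / scale^k
}

# Right-hand sides of the self-consistency system by nested adaptive
# quadrature: outer integral over the Gaussian disorder, inner oracle
# moments.
oracle_rhs <- function(theta, pi, zmax = 8) {
  zb <- pi$K - theta$mu * pi$h
  sz <- sqrt(pi$q_0) * theta$sigma
  m <- 1 - theta$beta * theta$sigma^2 * (pi$q_d - pi$q_0)
  if (theta$sigma == 0) {
    return(c(H = oracle_moment(m, zb, theta$beta, theta$nu, 1),
             Q_d = oracle_moment(m, zb, theta$beta, theta$nu, 2),
             Q_0 = oracle_moment(m, zb, theta$beta, theta$nu, 1)^2))
  }
  avg <- function(fun) {
    f <- Vectorize(function(z) stats::dnorm(z) * fun(zb + sz * z))
    stats::integrate(f, -zmax, zmax, rel.tol = 1e-9, abs.tol = 0)$value
  }
  c(H = avg(function(zeta) oracle_moment(m, zeta, theta$beta, theta$nu, 1)),
    Q_d = avg(function(zeta) oracle_moment(m, zeta, theta$beta, theta$nu, 2)),
    Q_0 = avg(function(zeta) oracle_moment(m, zeta, theta$beta, theta$nu, 1)^2))
}

# Disorder-averaged squared conditional variance (replicon integrand).
oracle_mean_var_sq <- function(theta, pi, zmax = 8) {
  zb <- pi$K - theta$mu * pi$h
  sz <- sqrt(pi$q_0) * theta$sigma
  m <- 1 - theta$beta * theta$sigma^2 * (pi$q_d - pi$q_0)
  f <- Vectorize(function(z) {
    zeta <- zb + sz * z
    v <- oracle_moment(m, zeta, theta$beta, theta$nu, 2) -
      oracle_moment(m, zeta, theta$beta, theta$nu, 1)^2
    stats::dnorm(z) * v^2
  })
  stats::integrate(f, -zmax, zmax, rel.tol = 1e-9, abs.tol = 0)$value
}

# Truncated-normal (lower bound 0) closed forms for the nu = 1 limit, in a
# cancellation-free arrangement: m1 = s (lambda - a) with the Mills ratio
# inverse lambda = sqrt(2/pi) / erfcx(a / sqrt(2)).
trunc_normal_moments <- function(m, zeta, beta) {
  s <- 1 / sqrt(beta * m)
  a <- -(zeta / m) / s
  lam <- sqrt(2 / pi) / pracma::erfcx(a / sqrt(2))
  delta <- lam - a
  m1 <- s * delta
  v <- s^2 * (1 - lam * delta)
  c(m1 = m1, m2 = v + m1^2)
}

# A small random compositional table with two cohorts.
random_table <- function(S = 30L, R = 12L, seed = 1L, zeros = 0.2) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    m <- matrix(stats::rexp(S * R), S, R)
    m[stats::runif(S * R) < zeros] <- 0
    # make sure no column dies
    for (j in which(colSums(m) == 0)) m[1, j] <- 1
    m <- sweep(m, 2L, colSums(m), `/`)
    abundance_table(m, cohort_labels = rep(c("A", "B"), length.out = R))
  })
}

# Standard fixtures
theta_weak <- function() model_parameters(mu = 1, sigma = 0.3, T = 5e-3, lam = 1e-5)
theta_mid <- function() model_parameters(mu = 1, sigma = 0.5, T = 2e-3, lam = 2e-4)
pi_mid <- function() solve_self_consistency(theta_mid(), K = 0.05)
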