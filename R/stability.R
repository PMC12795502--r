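# Stability and ecological-force diagnostics of an inferred (theta, pi):
# replicon eigenvalue, distance to the RSB line, niche-neutral ratio, and
# the pairwise interaction-distribution summary.

# Disorder-averaged squared conditional variance, int Dz Var(N|zeta(z))^2.
.mean_var_sq <- function(mu, sigma, beta, nu, h, q_d, q_0, K, nodes) {
  m <- 1 - beta * sigma^2 * (q_d - q_0)
  if (m <= 0) return(NULL)
  if (sigma == 0 || q_0 == 0) {
    cm <- .cond_moments(m, K - mu * h, beta, nu)
    return(cm$var^2)
  }
  gh <- gauss_hermite_probabilists(nodes)
  zeta <- K - mu * h + sqrt(q_0) * sigma * gh$z
  cm <- .cond_moments(m, zeta, beta, nu)
  sum(gh$w * cm$var^2)
}

#' Replicon eigenvalue of the replica-symmetric solution
#'
#' The leading eigenvalue of the critical sector of the replicated
#' free-energy Hessian:
#' \deqn{\mathcal{R} = (\beta\sigma)^2 \left(1 - (\beta\sigma)^2\,
#'   \overline{\big(\langle N^2\rangle - \langle N\rangle^2\big)^2}\right),}
#' where the overline is the Gaussian disorder average.  \eqn{\mathcal{R} \to 0}
#' signals marginal stability and the onset of replica-symmetry breaking;
#' communities with smaller \eqn{\mathcal{R}} are less robust to
#' perturbations.
#'
#' @inheritParams rhs_self_consistency
#' @return The replicon eigenvalue (a single number, `<= (beta*sigma)^2`).
#' @examples
#' theta <- model_parameters(1, 0.3, 5e-3, 1e-5)
#' pi <- solve_self_consistency(theta, K = 0.05)
#' replicon(theta, pi)
#' @export
replicon <- function(theta, pi, nodes = 101L) {
  theta <- .as_theta(theta)
  pi <- .as_pi(pi)
  if (theta$sigma == 0) return(0)
  v2 <- .mean_var_sq(theta$mu, theta$sigma, theta$beta, theta$nu,
                     pi$h, pi$q_d, pi$q_0, pi$K, nodes)
  if (is.null(v2)) {
    stop_dglvr("unbounded growth: mass m = %g <= 0",
               1 - theta$beta * theta$sigma^2 * (pi$q_d - pi$q_0))
  }
  bs2 <- (theta$beta * theta$sigma)^2
  bs2 * (1 - bs2 * v2)
}

#' Critical heterogeneity: distance to the replica-symmetry-breaking line
#'
#' Root-finds the value of \eqn{\sigma} (all other parameters and the order
#' parameters held fixed) at which the replicon eigenvalue crosses zero,
#' i.e. the nontrivial root of
#' \eqn{1 = (\beta\sigma)^2 \overline{\mathrm{Var}(N|\zeta)^2}}, by
#' bisection.  Optionally roots in \eqn{\beta} at fixed \eqn{\sigma}
#' instead.
#'
#' @inheritParams replicon
#' @param root_in Either `"sigma"` (default) or `"beta"`: the parameter
#'   varied to reach the RSB line.
#' @param upper Upper end of the bisection bracket (default 10 for sigma;
#'   for beta the bracket is scaled from the current value).
#' @param tol Bisection tolerance (default 1e-6).
#' @return A one-row tibble with `sigma_c` (or `beta_c`), the signed
#'   `distance` from the current value, the replicon `residual` at the root,
#'   and `crossing_found`.
#' @export
critical_sigma <- function(theta, pi, root_in = c("sigma", "beta"),
                           upper = NULL, tol = 1e-6, nodes = 101L) {
  theta <- .as_theta(theta)
  pi <- .as_pi(pi)
  root_in <- match.arg(root_in)

  # g(x) = 1 - (beta sigma)^2 * mean Var^2: positive in the stable phase.
  g <- function(sigma, beta) {
    v2 <- .mean_var_sq(theta$mu, sigma, beta, theta$nu,
                       pi$h, pi$q_d, pi$q_0, pi$K, nodes)
    if (is.null(v2)) return(NA_real_)   # unbounded-growth region
    1 - (beta * sigma)^2 * v2
  }

  if (root_in == "sigma") {
    upper <- upper %||% 10
    # the mass vanishes at sigma_m; stay strictly inside the physical region
    dq <- pi$q_d - pi$q_0
    sig_m <- if (dq > 0) sqrt(1 / (theta$beta * dq)) else Inf
    hi <- min(upper, 0.999999 * sig_m)
    lo <- max(min(theta$sigma, hi / 2), 1e-8)
    glo <- g(lo, theta$beta)
    while ((is.na(glo) || glo <= 0) && lo > 1e-12) {   # bracket from the stable side
      lo <- lo / 10
      glo <- g(lo, theta$beta)
    }
    ghi <- g(hi, theta$beta)
    if (is.na(glo) || glo <= 0 || is.na(ghi) || ghi >= 0) {
      return(tibble::tibble(sigma_c = NA_real_, distance = NA_real_,
                            residual = NA_real_, crossing_found = FALSE))
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      gm <- g(mid, theta$beta)
      if (is.na(gm) || gm <= 0) hi <- mid else lo <- mid
    }
    root <- (lo + hi) / 2
    tibble::tibble(sigma_c = root, distance = root - theta$sigma,
                   residual = replicon(model_parameters(theta$mu, root, theta$T,
                                                        theta$lam),
                                       pi, nodes = nodes),
                   crossing_found = TRUE)
  } else {
    # increase beta (lower T) toward the RSB line at fixed sigma
    if (theta$sigma <= 0) {
      return(tibble::tibble(beta_c = NA_real_, distance = NA_real_,
                            residual = NA_real_, crossing_found = FALSE))
    }
    dq <- pi$q_d - pi$q_0
    beta_m <- if (dq > 0) 1 / (theta$sigma^2 * dq) else Inf
    hi <- min(upper %||% (1e4 * theta$beta), 0.999999 * beta_m)
    lo <- theta$beta
    gb <- function(beta) {
      nu_b <- theta$lam * beta            # nu = beta * lam tracks beta
      v2 <- .mean_var_sq(theta$mu, theta$sigma, beta, nu_b,
                         pi$h, pi$q_d, pi$q_0, pi$K, nodes)
      if (is.null(v2)) return(NA_real_)
      1 - (beta * theta$sigma)^2 * v2
    }
    glo <- gb(lo); ghi <- gb(hi)
    if (is.na(glo) || glo <= 0 || is.na(ghi) || ghi >= 0) {
      return(tibble::tibble(beta_c = NA_real_, distance = NA_real_,
                            residual = NA_real_, crossing_found = FALSE))
    }
    while ((hi - lo) / hi > tol) {
      mid <- (lo + hi) / 2
      gm <- gb(mid)
      if (is.na(gm) || gm <= 0) hi <- mid else lo <- mid
    }
    root <- (lo + hi) / 2
    tibble::tibble(beta_c = root, distance = root - theta$beta,
                   residual = NA_real_, crossing_found = TRUE)
  }
}

#' Niche-neutral ratio
#'
#' The probability that a disorder realization's species abundance
#' distribution develops an interior mode -- the hallmark of
#' interaction-driven (niche) structuring against the neutral low-abundance
#' divergence:
#' \deqn{\psi = \tfrac12\,\mathrm{Erfc}\!\left(\frac{\zeta^* + \bar\zeta}
#'   {\sqrt{2}\sigma_\zeta}\right) + \tfrac12\,\mathrm{Erfc}\!\left(
#'   \frac{\zeta^* - \bar\zeta}{\sqrt{2}\sigma_\zeta}\right)
#'   = P(|\zeta| > \zeta^*),}
#' with \eqn{\zeta^* = \sqrt{4(1-\nu)m/\beta}}, \eqn{\bar\zeta = K - \mu h}
#' and \eqn{\sigma_\zeta = \sqrt{q_0}\,\sigma}.  Defined for \eqn{\nu < 1}
#' (demographic noise stronger than immigration); for \eqn{\nu \ge 1} the
#' distribution is always modal and \eqn{\zeta^*} is imaginary, so the
#' function refuses rather than extrapolates.
#'
#' @inheritParams replicon
#' @return \eqn{\psi \in [0, 1]}.
#' @export
niche_neutral_ratio <- function(theta, pi) {
  theta <- .as_theta(theta)
  pi <- .as_pi(pi)
  if (theta$nu >= 1) {
    stop_dglvr("modal regime: nu = %g >= 1, the niche-neutral ratio is undefined",
               theta$nu)
  }
  m <- 1 - theta$beta * theta$sigma^2 * (pi$q_d - pi$q_0)
  if (m <= 0) stop_dglvr("unbounded growth: mass m = %g is not positive", m)
  zeta_star <- sqrt(4 * (1 - theta$nu) * m / theta$beta)
  zeta_bar <- pi$K - theta$mu * pi$h
  sigma_zeta <- sqrt(pi$q_0) * theta$sigma
  if (sigma_zeta == 0) {
    return(as.numeric(abs(zeta_bar) > zeta_star))
  }
  # (1/2) Erfc(x / sqrt(2)) = P(Z > x)
  stats::pnorm((zeta_star + zeta_bar) / sigma_zeta, lower.tail = FALSE) +
    stats::pnorm((zeta_star - zeta_bar) / sigma_zeta, lower.tail = FALSE)
}

#' Pairwise interaction summary and sampled interaction matrix
#'
#' Converts the effective parameters to per-pair interaction statistics,
#' mean \eqn{\mu/S} and standard deviation \eqn{\sigma/\sqrt{S}}, and draws
#' one symmetric Gaussian interaction matrix with those marginals
#' (diagonal set to zero and excluded from the statistics).
#'
#' @param theta Model parameters (see [model_parameters()]).
#' @param S Species-pool size, `>= 2`.
#' @param seed Integer seed for the matrix draw.
#' @return A list with `mu_alpha`, `sigma_alpha`, `S` and the `S x S`
#'   symmetric matrix `alpha`.
#' @examples
#' interaction_summary(model_parameters(1, 0.5, 5e-3, 5e-4), S = 50, seed = 1)$mu_alpha
#' @export
interaction_summary <- function(theta, S, seed = 1L) {
  theta <- .as_theta(theta)
  S <- as.integer(S)
  if (S < 2L) stop_dglvr("species pool size S must be at least 2")
  mu_a <- theta$mu / S
  sd_a <- theta$sigma / sqrt(S)
  alpha <- with_local_seed(seed, {
    a <- matrix(0, S, S)
    up <- upper.tri(a)
    a[up] <- stats::rnorm(sum(up), mean = mu_a, sd = sd_a)
    a + t(a)
  })
  list(mu_alpha = mu_a, sigma_alpha = sd_a, S = S, alpha = alpha)
}

#' Stability metrics for one parameter set or a fitted ensemble
#'
#' Convenience wrapper computing, per parameter set: the replicon
#' eigenvalue, the mass, the niche-neutral ratio \eqn{\psi}, the critical
#' heterogeneity \eqn{\sigma_c} (RSB line at fixed \eqn{\beta}), and
#' \eqn{\zeta^*}.
#'
#' @param x A `dglv_fit` object (metrics per retained solution) or a single
#'   [model_parameters()] object.
#' @param pi Order parameters; taken from the fit when `x` is a `dglv_fit`.
#' @param nodes Gauss-Hermite nodes (default 101).
#' @param find_sigma_c Whether to root-find the RSB line per solution
#'   (default TRUE; the bisection is the slow part).
#' @return A tibble with one row per parameter set: `mu`, `sigma`, `T`,
#'   `lam`, `replicon`, `mass`, `psi`, `sigma_c`, `zeta_star`.
#' @export
stability_metrics <- function(x, pi = NULL, nodes = 101L, find_sigma_c = TRUE) {
  if (inherits(x, "dglv_fit")) {
    thetas <- purrr::pmap(x$solutions[, c("mu", "sigma", "T", "lam")],
                          model_parameters)
    pi <- pi %||% x$pi
  } else {
    thetas <- list(.as_theta(x))
    if (is.null(pi)) stop_dglvr("pi is required when x is a single parameter set")
  }
  pi <- .as_pi(pi)
  purrr::map_dfr(thetas, function(th) {
    m <- 1 - th$beta * th$sigma^2 * (pi$q_d - pi$q_0)
    rep_v <- if (m > 0) replicon(th, pi, nodes = nodes) else NA_real_
    psi_v <- if (m > 0 && th$nu < 1) niche_neutral_ratio(th, pi) else NA_real_
    zs <- if (m > 0 && th$nu < 1) sqrt(4 * (1 - th$nu) * m / th$beta) else NA_real_
    sc <- if (find_sigma_c && m > 0) {
      critical_sigma(th, pi, nodes = nodes)$sigma_c
    } else {
      NA_real_
    }
    tibble::tibble(mu = th$mu, sigma = th$sigma, T = th$T, lam = th$lam,
                   replicon = rep_v, mass = m, psi = psi_v,
                   sigma_c = sc, zeta_star = zs)
  })
}
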