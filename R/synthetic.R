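# Synthetic cohorts with the statistical structure the analysis assumes:
# stationary sampling from the cavity SAD (each sample is one disorder
# realization) and an explicit Euler-Maruyama integrator of the dgLV SDE.

# Inverse-CDF draws from the standardized law t^(nu-1) exp(-t^2/2 + b t):
# one uniform u per b.  Per-row grid in y = log t: an analytic-power-law
# head segment plus a dense bulk segment; trapezoid CDF, linear inversion.
.sample_std <- function(nu, b, u, n_head = 256L, n_bulk = 1280L) {
  n <- length(b)
  tstar <- (b + sqrt(b^2 + 4 * nu)) / 2
  y_hi <- log(tstar + 15)
  big <- b > 12
  eps <- pmin(0.5 / pmax(1, abs(b)), 0.7)
  y_mid <- ifelse(big, log(pmax(tstar - 14, tstar / 20)), log(eps))
  # below y_mid the density is ~ t^nu d(log t): take the head down to where
  # (t/eps)^nu = 1e-12, negligible mass below
  y_lo <- ifelse(big, y_mid, y_mid - 28 / nu)

  u_head <- seq(0, 1, length.out = n_head + 1L)[-(n_head + 1L)]
  u_bulk <- seq(0, 1, length.out = n_bulk)
  y <- cbind(y_lo + (y_mid - y_lo) %o% u_head,
             y_mid + (y_hi - y_mid) %o% u_bulk)
  tt <- exp(y)
  logg <- nu * y + b * tt - tt^2 / 2
  M <- logg[cbind(seq_len(n), max.col(logg, ties.method = "first"))]
  g <- exp(logg - M)

  G <- ncol(y)
  dy <- y[, -1L, drop = FALSE] - y[, -G, drop = FALSE]
  cellm <- (g[, -1L, drop = FALSE] + g[, -G, drop = FALSE]) / 2 * dy
  C <- cbind(0, t(apply(cellm, 1L, cumsum)))
  C <- C / C[, G]

  idx <- rowSums(C < u)             # u recycles per column: row-wise compare
  idx <- pmin(pmax(idx, 1L), G - 1L)
  c0 <- C[cbind(seq_len(n), idx)]
  c1 <- C[cbind(seq_len(n), idx + 1L)]
  y0 <- y[cbind(seq_len(n), idx)]
  y1 <- y[cbind(seq_len(n), idx + 1L)]
  frac <- ifelse(c1 > c0, (u - c0) / (c1 - c0), 0.5)
  exp(y0 + frac * (y1 - y0))
}

#' Sample a synthetic cohort from the stationary cavity theory
#'
#' Generates `R` samples of `S` species each: the forward self-consistency
#' fixed point of `theta` supplies \eqn{(h, q_0)}, each sample draws fresh
#' i.i.d. standard Gaussians \eqn{z_i} (its own realization of the
#' disorder), sets \eqn{\zeta_i = K - \mu h + \sqrt{q_0}\sigma z_i}, and
#' draws each abundance from the cavity law \eqn{p(N \mid \zeta_i)} by
#' inverse-CDF sampling on an adaptive log-abundance grid.  Optional
#' compositional closure and multinomial subsampling (which introduces the
#' zeros real profiling pipelines produce).
#'
#' The generator refuses \eqn{\nu = \beta\lambda < 0.05}: close to the
#' neutral divergence the low-abundance power law dominates the sampling
#' process and no representative finite sample exists.
#'
#' @inheritParams solve_self_consistency
#' @param S Species per community, `>= 2`.
#' @param R Number of samples (disorder realizations), `>= 1`.
#' @param compositional Close each sample to relative abundances summing
#'   to 1 (default `TRUE`).
#' @param subsample_depth Optional integer read depth; each sample is
#'   multinomially resampled at this depth, producing zeros.
#' @param seed Integer seed.
#' @return An `abundance_table`; the forward fixed point used is attached
#'   as attribute `"fixed_point"` and the parameters as `"theta"`.
#' @examples
#' theta <- model_parameters(1, 0.5, 2e-3, 2e-4)
#' tab <- sample_cohort_stationary(theta, K = 0.05, S = 50, R = 20, seed = 1)
#' @export
sample_cohort_stationary <- function(theta, K, S, R, compositional = TRUE,
                                     subsample_depth = NULL, seed = 1L,
                                     nodes = 101L) {
  theta <- .as_theta(theta)
  stopifnot(S >= 2L, R >= 1L, is_scalar_number(K), K > 0)
  if (theta$nu < 0.05) {
    stop_dglvr(paste0(
      "nu = beta*lambda = %g < 0.05: the low-abundance divergence dominates ",
      "the sampling process; the stationary generator refuses this regime"),
      theta$nu)
  }
  fp <- solve_self_consistency(theta, K, nodes = nodes)
  if (fp$m <= 0) stop_dglvr("unbounded growth: fixed-point mass m = %g", fp$m)

  scale <- sqrt(theta$beta * fp$m)
  zeta_bar <- K - theta$mu * fp$h
  sigma_zeta <- sqrt(fp$q_0) * theta$sigma

  N <- with_local_seed(seed, {
    total <- S * R
    z <- stats::rnorm(total)
    u <- stats::runif(total)
    b <- (zeta_bar + sigma_zeta * z) * theta$beta / scale
    out <- numeric(total)
    chunk <- 1000L
    for (start in seq(1L, total, by = chunk)) {
      iv <- start:min(start + chunk - 1L, total)
      out[iv] <- .sample_std(theta$nu, b[iv], u[iv])
    }
    matrix(out / scale, nrow = S, ncol = R)
  })

  if (!is.null(subsample_depth)) {
    stopifnot(subsample_depth >= 1)
    N <- with_local_seed(seed + 1L, {
      apply(N, 2L, function(col) {
        as.vector(stats::rmultinom(1L, subsample_depth, col / sum(col))) /
          subsample_depth
      })
    })
  } else if (compositional) {
    N <- sweep(N, 2L, colSums(N), `/`)
  }

  tab <- abundance_table(N, cohort_labels = rep("synthetic", R),
                         normalize = FALSE)
  attr(tab, "fixed_point") <- fp
  attr(tab, "theta") <- theta
  tab
}

#' Simulate the disordered Lotka-Volterra stochastic dynamics
#'
#' Explicit Euler-Maruyama integration (Ito convention) of
#' \deqn{dN_i = \left[N_i\big(K - N_i - \textstyle\sum_{j \ne i}
#'   \alpha_{ij} N_j\big) + \lambda\right] dt + \sqrt{2 T N_i}\, dW_i,}
#' with \eqn{\rho = 1} and a symmetric Gaussian interaction matrix drawn
#' with pairwise mean \eqn{\mu/S} and standard deviation
#' \eqn{\sigma/\sqrt{S}}.  Positivity is enforced by full truncation at a
#' small floor after each step; the immigration term pushes trajectories
#' off the floor.  Demographic noise may be zero (deterministic logistic
#' limit).
#'
#' Post-burn-in states are returned at snapshot intervals of at least five
#' autocorrelation times of the community mean abundance, estimated online
#' from the trajectory.
#'
#' @param theta Model parameters; a list with `mu`, `sigma`, `T`, `lam`
#'   (here `T >= 0` and `lam >= 0` are allowed, to reach the deterministic
#'   and closed-community limits).
#' @param K Carrying capacity.
#' @param S Number of species.
#' @param dt Time step (must satisfy `dt * K << 1`).
#' @param t_burnin Burn-in time discarded before snapshots.
#' @param t_total Total simulated time (`> t_burnin`).
#' @param floor Positivity floor (default 1e-12).
#' @param n_store Number of candidate state snapshots kept while running
#'   (default 2000); the decorrelated subset is returned.
#' @param N0 Optional initial abundances (default `K` for every species).
#' @param seed Integer seed.
#' @return A list with `table` (snapshots as an `abundance_table`, raw
#'   abundances, one column per retained snapshot), `mean_trace` (tibble
#'   `time`, `mean_abundance`), `tau` (estimated autocorrelation time), and
#'   `alpha` (the interaction matrix used).
#' @export
simulate_dglv_sde <- function(theta, K, S, dt = 5e-3, t_burnin = 50,
                              t_total = 250, floor = 1e-12, n_store = 2000L,
                              N0 = NULL, seed = 1L) {
  if (inherits(theta, "dglv_params")) theta <- unclass(theta)
  mu <- theta$mu; sigma <- theta$sigma; Tn <- theta$T; lam <- theta$lam
  stopifnot(is_scalar_number(mu), is_scalar_number(sigma), sigma >= 0,
            is_scalar_number(Tn), Tn >= 0, is_scalar_number(lam), lam >= 0,
            dt > 0, t_burnin < t_total, floor > 0, S >= 1L)
  if (dt * K > 0.1) {
    warning("dt * K > 0.1: the explicit scheme may be inaccurate", call. = FALSE)
  }

  n_steps <- ceiling(t_total / dt)
  burn_steps <- ceiling(t_burnin / dt)
  store_every <- max(1L, (n_steps - burn_steps) %/% n_store)  # note: `floor` arg shadows base

  with_local_seed(seed, {
    alpha <- if (S >= 2L) {
      a <- matrix(0, S, S)
      up <- upper.tri(a)
      a[up] <- stats::rnorm(sum(up), mu / S, if (S > 1) sigma / sqrt(S) else 0)
      a + t(a)
    } else {
      matrix(0, 1L, 1L)
    }

    N <- rep_len(N0 %||% K, S)
    sqrt2T <- sqrt(2 * Tn)
    states <- list()
    state_times <- numeric()
    mean_trace <- numeric(n_steps)

    for (step in seq_len(n_steps)) {
      inter <- drop(alpha %*% N)
      drift <- N * (K - N - inter) + lam
      if (Tn > 0) {
        N <- N + drift * dt + sqrt2T * sqrt(N * dt) * stats::rnorm(S)
      } else {
        N <- N + drift * dt
      }
      N[N < floor] <- floor
      if (any(N > 1e6 * K)) {
        stop_dglvr("unbounded growth detected at t = %.3g (max N = %.3g)",
                   step * dt, max(N))
      }
      mean_trace[step] <- mean(N)
      if (step > burn_steps && (step - burn_steps) %% store_every == 0L) {
        states[[length(states) + 1L]] <- N
        state_times <- c(state_times, step * dt)
      }
    }

    # integrated autocorrelation time of the mean-abundance trace (post burn-in)
    post <- mean_trace[(burn_steps + 1L):n_steps]
    tau <- dt
    if (length(post) > 50L && stats::sd(post) > 0) {
      ac <- stats::acf(post, lag.max = min(length(post) - 1L, 5000L),
                       plot = FALSE)$acf[, 1, 1]
      below <- which(ac < 0.05)
      lag_c <- if (length(below) > 0) below[1] else length(ac)
      tau <- max(dt, sum(ac[1:lag_c]) * dt)
    }

    keep_every <- max(1L, ceiling(5 * tau / (store_every * dt)))
    sel <- seq(1L, length(states), by = keep_every)
    snap <- do.call(cbind, states[sel])
    tab <- abundance_table(snap, cohort_labels = rep("sde", length(sel)),
                           sample_ids = paste0("t", signif(state_times[sel], 8)),
                           normalize = FALSE)
    list(table = tab,
         mean_trace = tibble::tibble(
           time = dt * seq_len(n_steps), mean_abundance = mean_trace),
         tau = tau, alpha = alpha,
         snapshot_times = state_times[sel])
  })
}

#' Parameter-recovery experiment on a synthetic cohort
#'
#' End-to-end check of the inference pipeline: generate a stationary cohort
#' at known parameters, estimate the order parameters from the synthetic
#' abundances, run the moment-matching fit, and compare the best solution
#' to the truth.  The carrying capacity handed to the fit is the
#' generator's `K` (the empirical max-based estimator is an extreme-value
#' statistic that grows with `R` and is only meaningful on real data).
#' Abundances are left unclosed so that the estimates target the forward
#' fixed point directly.
#'
#' @param theta_true True model parameters (interior to the bounds).
#' @param K Carrying capacity of the generator.
#' @param S,R Community size and number of samples (defaults 200, 500).
#' @param n_restarts,top_k,seed,nodes Passed to [fit_dglv()]; the same seed
#'   also drives the generator.
#' @return A list of class `dglv_recovery`: `theta_true`, `pi_hat`, `fit`,
#'   and `errors` (tibble with per-parameter relative errors of the best
#'   solution).
#' @export
parameter_recovery_experiment <- function(theta_true, K, S = 200L, R = 500L,
                                          n_restarts = 200L, top_k = 30L,
                                          seed = 1L, nodes = 101L) {
  theta_true <- .as_theta(theta_true)
  tab <- sample_cohort_stationary(theta_true, K = K, S = S, R = R,
                                  compositional = FALSE, seed = seed,
                                  nodes = nodes)
  est <- estimate_order_parameters(tab)
  pi_hat <- order_parameters(h = est$h, q_d = est$q_d, q_0 = est$q_0, K = K,
                             S_pool = est$S_pool, R = est$R,
                             cohort = "synthetic")
  fit <- fit_dglv(pi_hat, n_restarts = n_restarts, top_k = top_k, seed = seed,
                  nodes = nodes)
  best <- fit$solutions[1, ]
  truth <- c(mu = theta_true$mu, sigma = theta_true$sigma,
             T = theta_true$T, lam = theta_true$lam)
  est_v <- c(mu = best$mu, sigma = best$sigma, T = best$T, lam = best$lam)
  errors <- tibble::tibble(
    parameter = names(truth), true = unname(truth), estimate = unname(est_v),
    rel_error = unname(abs(est_v - truth) / abs(truth))
  )
  structure(list(theta_true = theta_true, pi_hat = pi_hat, fit = fit,
                 errors = errors, E_best = best$E, seed = seed),
            class = "dglv_recovery")
}

#' @export
print.dglv_recovery <- function(x, ...) {
  cat("<dglv_recovery>\n")
  cat(sprintf("  best-solution mean relative error E = %.3g\n", x$E_best))
  print(x$errors)
  invisible(x)
}
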