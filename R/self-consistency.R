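# Replica-symmetric self-consistency map and its fixed point.
#
# The RS order parameters obey
#   h   = int Dz E[N | zeta(z)]
#   q_d = int Dz E[N^2 | zeta(z)]
#   q_0 = int Dz (E[N | zeta(z)])^2
# with zeta(z) = K - mu h + sqrt(q_0) sigma z, the single-site expectations
# taken under p(N|zeta) with the mass built from the *input* order
# parameters.  The Gaussian z-average is a Gauss-Hermite sum.

# Fast internal one-step map: takes plain numbers, returns c(H, Qd, Q0).
# Returns NULL if the mass is non-positive.
.rhs_map <- function(mu, sigma, beta, nu, h, q_d, q_0, K, nodes) {
  m <- 1 - beta * sigma^2 * (q_d - q_0)
  if (m <= 0) return(NULL)
  if (sigma == 0) {
    cm <- .cond_moments(m, K - mu * h, beta, nu)
    return(c(H = cm$m1, Q_d = cm$m2, Q_0 = cm$m1^2))
  }
  gh <- gauss_hermite_probabilists(nodes)
  zeta <- K - mu * h + sqrt(q_0) * sigma * gh$z
  cm <- .cond_moments(m, zeta, beta, nu)
  c(H = sum(gh$w * cm$m1), Q_d = sum(gh$w * cm$m2), Q_0 = sum(gh$w * cm$m1^2))
}

#' One step of the replica-symmetric self-consistency map
#'
#' Evaluates the right-hand sides \eqn{(H, Q_d, Q_0)} of the RS
#' self-consistency system at model parameters `theta`, with the disorder
#' field \eqn{\zeta(z) = K - \mu h + \sqrt{q_0}\sigma z} and the mass built
#' from the input (e.g. empirical) order parameters.  At a solution of the
#' system, the output equals the input \eqn{(h, q_d, q_0)} -- this is the
#' map the moment-matching inference drives to agreement with the data.
#'
#' @inheritParams mass
#' @param nodes Number of Gauss-Hermite nodes for the disorder average
#'   (default 101).
#' @param adaptive If `TRUE` (default), the node count is doubled until the
#'   result changes by less than `1e-8` in relative terms.
#' @return A one-row tibble with columns `H`, `Q_d`, `Q_0`, `m` and `nodes`.
#' @examples
#' theta <- model_parameters(1, 0.3, 5e-3, 1e-5)
#' pi <- order_parameters(0.02, 1e-3, 4e-4, 0.05)
#' rhs_self_consistency(theta, pi)
#' @export
rhs_self_consistency <- function(theta, pi, nodes = 101L, adaptive = TRUE) {
  theta <- .as_theta(theta)
  pi <- .as_pi(pi)
  val <- .rhs_map(theta$mu, theta$sigma, theta$beta, theta$nu,
                  pi$h, pi$q_d, pi$q_0, pi$K, nodes)
  if (is.null(val)) {
    stop_dglvr("unbounded growth: mass m = %g <= 0 at the input order parameters",
               1 - theta$beta * theta$sigma^2 * (pi$q_d - pi$q_0))
  }
  used <- nodes
  if (adaptive && theta$sigma > 0) {
    repeat {
      nxt <- 2L * used + 1L
      val2 <- .rhs_map(theta$mu, theta$sigma, theta$beta, theta$nu,
                       pi$h, pi$q_d, pi$q_0, pi$K, nxt)
      drift <- max(abs(val2 - val) / pmax(abs(val), 1e-300))
      val <- val2
      used <- nxt
      if (drift <= 1e-8 || used > 1600L) break
    }
  }
  m <- 1 - theta$beta * theta$sigma^2 * (pi$q_d - pi$q_0)
  tibble::tibble(H = val[["H"]], Q_d = val[["Q_d"]], Q_0 = val[["Q_0"]],
                 m = m, nodes = used)
}

#' Solve the replica-symmetric self-consistency system
#'
#' Finds the theoretical fixed point \eqn{\pi^* = (h, q_d, q_0)} of the RS
#' self-consistency map for given model parameters and carrying capacity,
#' by damped fixed-point iteration
#' \eqn{\pi \leftarrow (1-\gamma)\pi + \gamma\,\mathrm{RHS}(\theta, \pi)}.
#'
#' @inheritParams rhs_self_consistency
#' @param K Carrying capacity, `> 0`.
#' @param init Optional starting order parameters; defaults to the
#'   non-interacting single-species moments at \eqn{\zeta = K}.
#' @param damping Damping factor \eqn{\gamma \in (0, 1]} (default 0.5).
#' @param tol Convergence tolerance on the maximum relative change
#'   (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return A one-row tibble with columns `h`, `q_d`, `q_0`, `K`, `m`,
#'   `iterations` and `converged`.
#' @examples
#' theta <- model_parameters(1, 0.3, 5e-3, 1e-5)
#' solve_self_consistency(theta, K = 0.05)
#' @export
solve_self_consistency <- function(theta, K, init = NULL, damping = 0.5,
                                   tol = 1e-10, max_iter = 10000L,
                                   nodes = 101L) {
  theta <- .as_theta(theta)
  stopifnot(is_scalar_number(K), K > 0, damping > 0, damping <= 1)

  if (is.null(init)) {
    cm <- .cond_moments(1, K, theta$beta, theta$nu)
    pi_cur <- c(cm$m1, cm$m2, cm$m1^2)
  } else {
    init <- .as_pi(init)
    pi_cur <- c(init$h, init$q_d, init$q_0)
  }

  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    val <- .rhs_map(theta$mu, theta$sigma, theta$beta, theta$nu,
                    pi_cur[1], pi_cur[2], pi_cur[3], K, nodes)
    if (is.null(val)) {
      stop_dglvr(paste0(
        "unbounded growth regime: mass became non-positive at iteration %d ",
        "(h = %g, q_d = %g, q_0 = %g)"), it, pi_cur[1], pi_cur[2], pi_cur[3])
    }
    pi_new <- (1 - damping) * pi_cur + damping * unname(val)
    rel <- max(abs(pi_new - pi_cur) / pmax(abs(pi_cur), 1e-300))
    pi_cur <- pi_new
    if (rel <= tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop_dglvr(paste0(
      "self-consistency iteration did not converge in %d steps ",
      "(last relative change %.3g; h = %g, q_d = %g, q_0 = %g)"),
      max_iter, rel, pi_cur[1], pi_cur[2], pi_cur[3])
  }
  m <- 1 - theta$beta * theta$sigma^2 * (pi_cur[2] - pi_cur[3])
  tibble::tibble(h = pi_cur[1], q_d = pi_cur[2], q_0 = pi_cur[3], K = K,
                 m = m, iterations = it, converged = converged)
}
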