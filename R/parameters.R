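#' Effective ecological parameters of the disordered Lotka-Volterra model
#'
#' Bundles \eqn{\theta = (\mu, \sigma, T, \lambda)}: the mean interaction
#' scale \eqn{\mu} (pairwise mean is \eqn{\mu/S}), the interaction
#' heterogeneity \eqn{\sigma} (pairwise standard deviation \eqn{\sigma/\sqrt S}),
#' the demographic noise amplitude \eqn{T} and the immigration rate
#' \eqn{\lambda}.  The derived quantities \eqn{\beta = 1/T} (inverse noise)
#' and \eqn{\nu = \beta\lambda} (low-abundance exponent of the species
#' abundance distribution) are stored alongside.
#'
#' @param mu Mean interaction scale (dimensionless).
#' @param sigma Interaction heterogeneity, `>= 0`.
#' @param T Demographic noise amplitude, `> 0`.
#' @param lam Immigration rate, `> 0`.
#' @return An object of class `dglv_params`.
#' @examples
#' model_parameters(mu = 1, sigma = 0.5, T = 5e-3, lam = 5e-4)
#' @export
model_parameters <- function(mu, sigma, T, lam) {
  stopifnot(is_scalar_number(mu), is_scalar_number(sigma),
            is_scalar_number(T), is_scalar_number(lam))
  if (T <= 0) stop_dglvr("demographic noise T must be positive (got %g)", T)
  if (lam <= 0) stop_dglvr("immigration rate lam must be positive (got %g)", lam)
  if (sigma < 0) stop_dglvr("interaction heterogeneity sigma must be >= 0 (got %g)", sigma)
  structure(
    list(mu = mu, sigma = sigma, T = T, lam = lam, beta = 1 / T, nu = lam / T),
    class = "dglv_params"
  )
}

#' @export
print.dglv_params <- function(x, ...) {
  cat("<dglv_params>\n")
  cat(sprintf("  mu = %g, sigma = %g, T = %g, lam = %g\n", x$mu, x$sigma, x$T, x$lam))
  cat(sprintf("  beta = 1/T = %g, nu = beta*lam = %g\n", x$beta, x$nu))
  invisible(x)
}

#' @export
as.list.dglv_params <- function(x, ...) unclass(x)

# Coerce user input to a dglv_params object.
.as_theta <- function(theta) {
  if (inherits(theta, "dglv_params")) return(theta)
  if (is.data.frame(theta)) {
    if (nrow(theta) != 1L) stop_dglvr("theta data frame must have exactly one row")
    theta <- as.list(theta)
  }
  if (is.numeric(theta)) theta <- as.list(theta)
  need <- c("mu", "sigma", "T", "lam")
  if (!all(need %in% names(theta))) {
    stop_dglvr("theta needs components %s", paste(need, collapse = ", "))
  }
  model_parameters(theta$mu, theta$sigma, theta$T, theta$lam)
}

#' Macroecological order parameters of a cohort
#'
#' Constructs the macrostate vector \eqn{\pi = (h, q_d, q_0, K)}: mean
#' abundance, self-overlap, overlap and carrying capacity, on the
#' relative-abundance scale.  These are the quantities the self-consistency
#' map reproduces and the moment-matching inference consumes.
#'
#' @param h Mean abundance, `> 0`.
#' @param q_d Self-overlap (mean squared abundance within a sample).
#' @param q_0 Overlap (mean of squared per-sample mean abundance),
#'   `0 < q_0 <= q_d`.
#' @param K Carrying capacity (mean over species of the maximum relative
#'   abundance across samples), `> 0`.
#' @param S_pool Optional species-pool size.
#' @param R Optional number of samples.
#' @param cohort Optional cohort label.
#' @return A one-row tibble with the order parameters.
#' @examples
#' order_parameters(h = 0.02, q_d = 2e-3, q_0 = 6e-4, K = 0.05)
#' @export
order_parameters <- function(h, q_d, q_0, K, S_pool = NA_integer_,
                             R = NA_integer_, cohort = NA_character_) {
  stopifnot(is_scalar_number(h), is_scalar_number(q_d),
            is_scalar_number(q_0), is_scalar_number(K))
  if (h <= 0) stop_dglvr("h must be positive")
  if (q_0 <= 0) stop_dglvr("q_0 must be positive")
  if (q_d < q_0) stop_dglvr("q_d (%g) must be >= q_0 (%g)", q_d, q_0)
  if (K <= 0) stop_dglvr("K must be positive")
  tibble::tibble(cohort = cohort, h = h, q_d = q_d, q_0 = q_0, K = K,
                 S_pool = as.integer(S_pool), R = as.integer(R))
}

# Coerce a one-row tibble / named list / named vector to a plain list with
# h, q_d, q_0, K.
.as_pi <- function(pi) {
  if (is.data.frame(pi)) {
    if (nrow(pi) != 1L) {
      stop_dglvr("order parameters must be a single row (got %d); filter to one cohort first",
                 nrow(pi))
    }
    pi <- as.list(pi)
  }
  if (is.numeric(pi)) pi <- as.list(pi)
  need <- c("h", "q_d", "q_0", "K")
  if (!all(need %in% names(pi))) {
    stop_dglvr("order parameters need components %s", paste(need, collapse = ", "))
  }
  if (pi$h <= 0 || pi$q_0 <= 0 || pi$K <= 0 || pi$q_d < pi$q_0) {
    stop_dglvr("invalid order parameters: need h > 0, K > 0, q_d >= q_0 > 0")
  }
  pi[need]
}

#' Mass term of the replica-symmetric theory
#'
#' \eqn{m = 1 - \beta \sigma^2 (q_d - q_0)}.  The mass must stay positive
#' for the theory to be consistent; \eqn{m \to 0} marks the transition to
#' the unbounded-growth regime, so a non-positive value is reported with a
#' warning (attribute `physical` set to `FALSE`) rather than an error --
#' callers use it as a phase diagnostic.
#'
#' @param theta Model parameters (see [model_parameters()]).
#' @param pi Order parameters (see [order_parameters()]).
#' @return The mass, a single number with attribute `physical`.
#' @examples
#' mass(model_parameters(1, 0.5, 5e-3, 5e-4),
#'      order_parameters(0.02, 2e-3, 6e-4, 0.05))
#' @export
mass <- function(theta, pi) {
  theta <- .as_theta(theta)
  pi <- .as_pi(pi)
  m <- 1 - theta$beta * theta$sigma^2 * (pi$q_d - pi$q_0)
  if (m <= 0) {
    warning(sprintf("mass m = %g <= 0: unbounded-growth regime", m), call. = FALSE)
  }
  structure(m, physical = m > 0)
}

#' Parameters of the single-site species abundance distribution
#'
#' Collects the parameters of the cavity law
#' \eqn{p(N \mid \zeta) \propto N^{\nu-1} \exp\{-\beta(m N^2/2 - \zeta N)\}}
#' with Gaussian disorder \eqn{\zeta = \bar\zeta + \sigma_\zeta z}:
#' the exponent \eqn{\nu}, inverse noise \eqn{\beta}, mass \eqn{m}, mean
#' disorder \eqn{\bar\zeta = K - \mu h} and disorder scale
#' \eqn{\sigma_\zeta = \sqrt{q_0}\,\sigma}.
#'
#' @inheritParams mass
#' @return An object of class `sad_params`.
#' @export
sad_parameters <- function(theta, pi) {
  theta <- .as_theta(theta)
  pi <- .as_pi(pi)
  m <- 1 - theta$beta * theta$sigma^2 * (pi$q_d - pi$q_0)
  structure(
    list(nu = theta$nu, beta = theta$beta, m = m,
         zeta_bar = pi$K - theta$mu * pi$h,
         sigma_zeta = sqrt(pi$q_0) * theta$sigma),
    class = "sad_params"
  )
}

#' @export
print.sad_params <- function(x, ...) {
  cat("<sad_params>\n")
  cat(sprintf("  nu = %g, beta = %g, m = %g\n", x$nu, x$beta, x$m))
  cat(sprintf("  zeta_bar = %g, sigma_zeta = %g\n", x$zeta_bar, x$sigma_zeta))
  invisible(x)
}
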