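# Species abundance distribution of the single-site cavity theory.

# log density of p(N | zeta) at abundances N (vector), normalized.
.log_sad_conditional <- function(N, nu, beta, m, zeta) {
  scale <- sqrt(beta * m)
  res <- .std_moments(nu, zeta * beta / scale, k_max = 0L)
  log_z <- res$log_norm - nu * log(scale)   # log of the normalizing integral
  (nu - 1) * log(N) - beta * (m * N^2 / 2 - zeta * N) - log_z
}

#' Species abundance distribution density
#'
#' Evaluates the normalized cavity species abundance distribution on a grid
#' of abundances, either at the mean disorder \eqn{\bar\zeta = K - \mu h}
#' (the fixed-disorder curve) or marginalized over the Gaussian
#' disorder \eqn{\zeta = \bar\zeta + \sigma_\zeta z} by Gauss-Hermite
#' quadrature.
#'
#' For \eqn{\nu < 1} the density diverges as \eqn{N^{\nu-1}} when
#' \eqn{N \to 0} -- an integrable, low-abundance divergence signalling
#' neutral-like dynamics; for \eqn{\nu > 1} the distribution is modal.
#'
#' @param params SAD parameters from [sad_parameters()] (or a list with
#'   fields `nu`, `beta`, `m`, `zeta_bar`, `sigma_zeta`).
#' @param grid Strictly positive abundance values at which to evaluate.
#' @param at_mean_disorder If `TRUE` (default), fix \eqn{\zeta = \bar\zeta};
#'   otherwise return the disorder-marginalized density.
#' @param nodes Gauss-Hermite nodes for the marginal (default 101).
#' @return A tibble with columns `N` and `density`.
#' @examples
#' p <- sad_parameters(model_parameters(1, 0.3, 5e-3, 1e-3),
#'                     order_parameters(0.02, 1e-3, 4e-4, 0.05))
#' sad_density(p, grid = seq(1e-4, 0.2, length.out = 50))
#' @export
sad_density <- function(params, grid, at_mean_disorder = TRUE, nodes = 101L) {
  stopifnot(is.list(params))
  need <- c("nu", "beta", "m", "zeta_bar", "sigma_zeta")
  if (!all(need %in% names(params))) {
    stop_dglvr("params needs components %s (see sad_parameters())",
               paste(need, collapse = ", "))
  }
  if (params$m <= 0) stop_dglvr("unbounded growth: mass m = %g is not positive", params$m)
  if (any(grid <= 0)) stop_dglvr("grid abundances must be strictly positive")

  if (at_mean_disorder || params$sigma_zeta == 0) {
    dens <- exp(.log_sad_conditional(grid, params$nu, params$beta, params$m,
                                     params$zeta_bar))
  } else {
    gh <- gauss_hermite_probabilists(nodes)
    zeta <- params$zeta_bar + params$sigma_zeta * gh$z
    dens <- rep(0, length(grid))
    for (g in seq_along(zeta)) {
      dens <- dens + gh$w[g] *
        exp(.log_sad_conditional(grid, params$nu, params$beta, params$m, zeta[g]))
    }
  }
  tibble::tibble(N = grid, density = dens)
}
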