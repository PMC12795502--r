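# Internal numerical utilities: cached quadrature rules, log-domain helpers,
# and a local RNG scope so seeded functions do not disturb the caller's stream.

.dglvr_env <- new.env(parent = emptyenv())

# Gauss-Hermite rule for integrals against the standard Gaussian measure Dz:
# int Dz f(z) = sum(w * f(z)), with nodes z = sqrt(2) x and w = w_GH / sqrt(pi).
gauss_hermite_probabilists <- function(n) {
  key <- paste0("gh", n)
  rule <- .dglvr_env[[key]]
  if (is.null(rule)) {
    gh <- pracma::gaussHermite(n)
    rule <- list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
    .dglvr_env[[key]] <- rule
  }
  rule
}

# Composite Gauss-Legendre base rule on [0, 1]: `panels` equal panels of
# `n_per` nodes each.  Returned as (u, w) with sum(w) = 1.
gauss_legendre_composite <- function(panels, n_per) {
  key <- paste0("gl", panels, "_", n_per)
  rule <- .dglvr_env[[key]]
  if (is.null(rule)) {
    gl <- pracma::gaussLegendre(n_per, 0, 1)
    u <- as.vector(outer(gl$x / panels, (seq_len(panels) - 1) / panels, `+`))
    w <- rep(gl$w / panels, panels)
    rule <- list(u = u, w = w)
    .dglvr_env[[key]] <- rule
  }
  rule
}

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[a == -Inf & b == -Inf] <- -Inf
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_dglvr <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}
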