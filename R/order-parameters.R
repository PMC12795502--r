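# Empirical order parameters of a cohort, with bootstrap uncertainty and
# label-randomization nulls.
#
#   h   = (1/R) sum_a (1/S_a) sum_j N_{j,a}
#   q_d = (1/R) sum_a (1/S_a) sum_j N_{j,a}^2
#   q_0 = (1/R) sum_a ((1/S_a) sum_j N_{j,a})^2
#   K   = (1/S) sum_j max_a N_{j,a}
#
# S_a counts species with strictly positive abundance in sample a (zeros are
# structural absences for the divisor but contribute 0 to the sums); the
# species pool S is the set of species observed in at least one sample of
# the cohort.  On compositional data these imply h = mean(1/S_a) and
# q_0 = mean(1/S_a^2) exactly.

# Core estimator on a plain species x samples matrix.
.op_core <- function(A) {
  Sa <- colSums(A > 0)
  if (any(Sa == 0)) stop_dglvr("sample with no observed species")
  mean_a <- colSums(A) / Sa
  h <- mean(mean_a)
  q_d <- mean(colSums(A^2) / Sa)
  q_0 <- mean(mean_a^2)
  rmax <- do.call(pmax, lapply(seq_len(ncol(A)), function(j) A[, j]))
  pool <- rmax > 0
  K <- sum(rmax) / sum(pool)
  list(h = h, q_d = q_d, q_0 = q_0, K = K,
       S_pool = sum(pool), R = ncol(A))
}

#' Estimate the macroecological order parameters of each cohort
#'
#' Computes the mean abundance \eqn{h}, self-overlap \eqn{q_d}, overlap
#' \eqn{q_0} and carrying capacity \eqn{K} from a species-by-sample
#' abundance table, per cohort: the ensemble average is taken over species
#' within a sample (neutral hypothesis) and the disorder average over
#' samples.  \eqn{K} is the mean over the cohort's species pool of each
#' species' maximum relative abundance across samples.
#'
#' On compositional data, \eqn{h} equals the mean of \eqn{1/S_a} and
#' \eqn{q_0} the mean of \eqn{1/S_a^2} (with \eqn{S_a} the number of
#' species observed in sample \eqn{a}), so \eqn{h} is a direct measure of
#' average local diversity.
#'
#' @param table An [abundance_table()] (or long tibble accepted by
#'   [as_abundance_table()]).
#' @param cohort Optional label(s) restricting the estimate to given
#'   cohort(s); default all cohorts present.
#' @return A tibble with one row per cohort: `cohort`, `h`, `q_d`, `q_0`,
#'   `K`, `S_pool`, `R`.
#' @examples
#' m <- matrix(c(0.5, 0.3, 0.2, 0.9, 0.1, 0), nrow = 3)
#' estimate_order_parameters(abundance_table(m))
#' @export
estimate_order_parameters <- function(table, cohort = NULL) {
  table <- as_abundance_table(table)
  cohorts <- cohort %||% unique(table$cohort_labels)
  missing <- setdiff(cohorts, table$cohort_labels)
  if (length(missing) > 0) {
    stop_dglvr("no samples for cohort(s): %s", paste(missing, collapse = ", "))
  }
  purrr::map_dfr(cohorts, function(cc) {
    A <- table$abundances[, table$cohort_labels == cc, drop = FALSE]
    op <- .op_core(A)
    tibble::tibble(cohort = cc, h = op$h, q_d = op$q_d, q_0 = op$q_0,
                   K = op$K, S_pool = op$S_pool, R = op$R)
  })
}

#' Bootstrap uncertainty of the order parameters
#'
#' Repeatedly re-estimates the order parameters on random subsets of each
#' cohort's samples: each iteration retains
#' \eqn{\lfloor \mathrm{retain\_fraction} \cdot R \rfloor} samples
#' (without replacement by default; set `replace = TRUE` for a classical
#' bootstrap) and recomputes the estimators.  The reference protocol is
#' 5000 iterations retaining 90% of samples within each cohort.
#'
#' @inheritParams estimate_order_parameters
#' @param n_iter Number of bootstrap iterations (default 5000).
#' @param retain_fraction Fraction of samples retained per iteration, in
#'   (0, 1] (default 0.9).
#' @param seed Integer seed (reproducible draws).
#' @param replace Resample with replacement instead of subsampling.
#' @return An object of class `dglv_bootstrap`: use `tidy()` for the
#'   per-iteration draws, `glance()` for per-parameter mean and standard
#'   deviation, `autoplot()` for the cohort comparison.
#' @export
bootstrap_order_parameters <- function(table, cohort = NULL, n_iter = 5000L,
                                       retain_fraction = 0.9, seed = 1L,
                                       replace = FALSE) {
  table <- as_abundance_table(table)
  stopifnot(n_iter >= 1L, retain_fraction > 0, retain_fraction <= 1)
  cohorts <- cohort %||% unique(table$cohort_labels)
  observed <- estimate_order_parameters(table, cohorts)

  draws <- with_local_seed(seed, {
    purrr::map_dfr(cohorts, function(cc) {
      A <- table$abundances[, table$cohort_labels == cc, drop = FALSE]
      R <- ncol(A)
      n_keep <- floor(retain_fraction * R)
      if (n_keep == 0) {
        stop_dglvr("retain_fraction %.3g keeps zero of the %d samples in cohort %s",
                   retain_fraction, R, cc)
      }
      purrr::map_dfr(seq_len(n_iter), function(it) {
        idx <- sample.int(R, n_keep, replace = replace)
        op <- .op_core(A[, idx, drop = FALSE])
        tibble::tibble(cohort = cc, iter = it, h = op$h, q_d = op$q_d,
                       q_0 = op$q_0, K = op$K)
      })
    })
  })

  summary <- draws |>
    tidyr::pivot_longer(c("h", "q_d", "q_0", "K"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$cohort, .data$parameter) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")

  structure(
    list(draws = draws, summary = summary, observed = observed,
         n_iter = n_iter, retain_fraction = retain_fraction,
         seed = seed, replace = replace),
    class = "dglv_bootstrap"
  )
}

#' @export
print.dglv_bootstrap <- function(x, ...) {
  cat(sprintf("<dglv_bootstrap> %d iterations, retaining %.0f%% of samples\n",
              x$n_iter, 100 * x$retain_fraction))
  print(x$summary)
  invisible(x)
}

#' @rdname bootstrap_order_parameters
#' @param x A `dglv_bootstrap` object.
#' @param ... Unused.
#' @export
tidy.dglv_bootstrap <- function(x, ...) x$draws

#' @rdname bootstrap_order_parameters
#' @export
glance.dglv_bootstrap <- function(x, ...) x$summary

#' @rdname bootstrap_order_parameters
#' @param object A `dglv_bootstrap` object.
#' @export
autoplot.dglv_bootstrap <- function(object, ...) {
  obs <- object$observed |>
    tidyr::pivot_longer(c("h", "q_d", "q_0", "K"),
                        names_to = "parameter", values_to = "value")
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$cohort, y = .data$mean,
                               colour = .data$cohort)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$value),
                        shape = 4, size = 3, colour = "black") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "order parameter") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Label-randomization null distributions of the order parameters
#'
#' Permutes the cohort labels across all samples (preserving cohort sizes)
#' and re-estimates the order parameters per permuted cohort, building the
#' null distribution against which the observed cohort differences are
#' judged.
#'
#' @inheritParams bootstrap_order_parameters
#' @param n_iter Number of label permutations (default 1000).
#' @return An object of class `dglv_null` with per-iteration draws
#'   (`tidy()`), observed values, and an `autoplot()` comparison.
#' @export
label_randomization_null <- function(table, n_iter = 1000L, seed = 1L) {
  table <- as_abundance_table(table)
  cohorts <- unique(table$cohort_labels)
  if (length(cohorts) < 2L) {
    stop_dglvr("label randomization needs at least 2 cohorts (found %d)",
               length(cohorts))
  }
  observed <- estimate_order_parameters(table)
  labels <- table$cohort_labels
  draws <- with_local_seed(seed, {
    purrr::map_dfr(seq_len(n_iter), function(it) {
      perm <- sample(labels)
      purrr::map_dfr(cohorts, function(cc) {
        A <- table$abundances[, perm == cc, drop = FALSE]
        op <- .op_core(A)
        tibble::tibble(iter = it, cohort = cc, h = op$h, q_d = op$q_d,
                       q_0 = op$q_0, K = op$K)
      })
    })
  })
  structure(list(draws = draws, observed = observed, n_iter = n_iter,
                 seed = seed),
            class = "dglv_null")
}

#' @export
print.dglv_null <- function(x, ...) {
  cat(sprintf("<dglv_null> %d label permutations, %d cohorts\n",
              x$n_iter, nrow(x$observed)))
  invisible(x)
}

#' @rdname label_randomization_null
#' @param x A `dglv_null` object.
#' @param ... Unused.
#' @export
tidy.dglv_null <- function(x, ...) x$draws

#' @rdname label_randomization_null
#' @param object A `dglv_null` object.
#' @export
autoplot.dglv_null <- function(object, ...) {
  long <- object$draws |>
    tidyr::pivot_longer(c("h", "q_d", "q_0", "K"),
                        names_to = "parameter", values_to = "value")
  obs <- object$observed |>
    tidyr::pivot_longer(c("h", "q_d", "q_0", "K"),
                        names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cohort, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey80", colour = NA) +
    ggplot2::geom_point(data = obs, colour = "red", size = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "order parameter (null in grey, observed in red)") +
    ggplot2::theme_minimal()
}
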