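# End-to-end orchestration: estimate -> fit -> stability -> report, per
# cohort, with a machine-readable manifest.

#' Run the full macroecological analysis pipeline
#'
#' Per cohort: estimates the order parameters with bootstrap uncertainty,
#' inverts them by moment matching, and computes the stability diagnostics
#' (replicon eigenvalue, mass, niche-neutral ratio, distance to the RSB
#' line) for every retained solution.  With at least two cohorts, the
#' label-randomization null is added.  All stages derive their seeds from
#' the single `seed`, so the pipeline is a pure function of
#' (inputs, configuration).
#'
#' @param table An [abundance_table()] (or path to one, read with
#'   [read_abundance_table()]).
#' @param fit Run the moment-matching stage (default `TRUE`); when `FALSE`,
#'   only the order-parameter stage (and bootstrap/null) is emitted.
#' @param stability Run the stability stage per solution (default `TRUE`;
#'   requires `fit`).
#' @param bootstrap_iter Bootstrap iterations (default 1000; the reference
#'   protocol uses 5000).
#' @param retain_fraction Bootstrap retention fraction (default 0.9).
#' @param null_iter Label-permutation iterations when >= 2 cohorts
#'   (default 200; 0 disables).
#' @param n_restarts,top_k Moment-matching protocol per cohort.
#' @param find_sigma_c Root-find the RSB line per solution (default `TRUE`).
#' @param nodes Gauss-Hermite nodes.
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, CSV/JSON artifacts are
#'   written (`order_parameters.csv`, `bootstrap_summary.csv`,
#'   `solutions.csv`, `stability.csv`, `manifest.json`).
#' @return An object of class `dglv_pipeline` with elements
#'   `order_parameters`, `bootstrap`, `null`, `fits` (named list of
#'   `dglv_fit`), `solutions`, `stability` and `manifest`.
#' @export
run_dglv_pipeline <- function(table, fit = TRUE, stability = TRUE,
                              bootstrap_iter = 1000L, retain_fraction = 0.9,
                              null_iter = 200L, n_restarts = 200L,
                              top_k = 30L, find_sigma_c = TRUE,
                              nodes = 101L, seed = 1L, out_dir = NULL) {
  if (is.character(table)) table <- read_abundance_table(table)
  table <- as_abundance_table(table)
  cohorts <- unique(table$cohort_labels)

  config <- list(fit = fit, stability = stability,
                 bootstrap_iter = bootstrap_iter,
                 retain_fraction = retain_fraction, null_iter = null_iter,
                 n_restarts = n_restarts, top_k = top_k,
                 find_sigma_c = find_sigma_c, nodes = nodes, seed = seed)

  ops <- estimate_order_parameters(table)
  boot <- if (bootstrap_iter > 0) {
    bootstrap_order_parameters(table, n_iter = bootstrap_iter,
                               retain_fraction = retain_fraction,
                               seed = seed + 1L)
  }
  null <- if (length(cohorts) >= 2L && null_iter > 0) {
    label_randomization_null(table, n_iter = null_iter, seed = seed + 2L)
  }

  fits <- NULL
  solutions <- NULL
  stab <- NULL
  if (fit) {
    fits <- purrr::map(seq_along(cohorts), function(i) {
      fit_dglv(ops[ops$cohort == cohorts[i], ], n_restarts = n_restarts,
               top_k = top_k, seed = seed + 10L + i, nodes = nodes)
    })
    names(fits) <- cohorts
    solutions <- purrr::imap_dfr(fits, function(f, cc) {
      dplyr::mutate(f$solutions, cohort = cc, .before = 1L)
    })
    if (stability) {
      stab <- purrr::imap_dfr(fits, function(f, cc) {
        dplyr::mutate(
          stability_metrics(f, nodes = nodes, find_sigma_c = find_sigma_c),
          cohort = cc, .before = 1L)
      })
    }
  }

  manifest <- list(
    package = "dglvr",
    version = as.character(utils::packageVersion("dglvr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = NULL,   # kept NULL so reruns hash identically
    seed = seed,
    config = config,
    cohorts = as.list(table(table$cohort_labels)),
    input_hash = rlang::hash(table$abundances),
    label_hash = rlang::hash(table$cohort_labels),
    result_hash = rlang::hash(list(ops, solutions, stab))
  )

  out <- structure(
    list(order_parameters = ops, bootstrap = boot, null = null, fits = fits,
         solutions = solutions, stability = stab, manifest = manifest),
    class = "dglv_pipeline"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(ops, file.path(out_dir, "order_parameters.csv"))
    if (!is.null(boot)) {
      readr::write_csv(boot$summary, file.path(out_dir, "bootstrap_summary.csv"))
    }
    if (!is.null(solutions)) {
      readr::write_csv(solutions, file.path(out_dir, "solutions.csv"))
    }
    if (!is.null(stab)) {
      readr::write_csv(stab, file.path(out_dir, "stability.csv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.dglv_pipeline <- function(x, ...) {
  cat("<dglv_pipeline>\n")
  cat(sprintf("  cohorts: %s\n", paste(x$order_parameters$cohort, collapse = ", ")))
  print(x$order_parameters)
  if (!is.null(x$solutions)) {
    best <- x$solutions |>
      dplyr::group_by(.data$cohort) |>
      dplyr::slice_min(.data$cost, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup()
    cat("  best solutions per cohort:\n")
    print(best[, c("cohort", "mu", "sigma", "T", "lam", "cost", "E")])
  }
  invisible(x)
}

#' Plot pipeline results in the stability planes
#'
#' Retained solutions per cohort in the \eqn{(T, \sigma)} plane, or the
#' \eqn{(\psi, m)} plane when stability metrics are present.
#'
#' @param object A `dglv_pipeline` object.
#' @param plane `"T_sigma"` (default) or `"psi_mass"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dglv_pipeline <- function(object, plane = c("T_sigma", "psi_mass"), ...) {
  plane <- match.arg(plane)
  if (plane == "T_sigma") {
    if (is.null(object$solutions)) stop_dglvr("pipeline was run without the fit stage")
    ggplot2::ggplot(object$solutions,
                    ggplot2::aes(x = .data$T, y = .data$sigma,
                                 colour = .data$cohort,
                                 alpha = -log10(.data$cost))) +
      ggplot2::geom_point(size = 2) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "demographic noise T", y = "interaction heterogeneity σ") +
      ggplot2::theme_minimal()
  } else {
    if (is.null(object$stability)) stop_dglvr("pipeline was run without the stability stage")
    ggplot2::ggplot(object$stability,
                    ggplot2::aes(x = .data$psi, y = .data$mass,
                                 colour = .data$cohort)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = expression(psi), y = "mass m") +
      ggplot2::theme_minimal()
  }
}
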