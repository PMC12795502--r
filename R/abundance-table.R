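# Compositional species x sample abundance tables with cohort labels: the
# empirical object all estimators consume.

#' Construct an abundance table
#'
#' Validates and (if needed) renormalizes a species-by-sample matrix of
#' relative abundances with one cohort label per sample.  Columns whose
#' total deviates from 1 by more than `1e-6` are renormalized to sum to 1,
#' with a warning -- count tables are therefore accepted and closed.
#'
#' @param abundances Nonnegative numeric matrix, species in rows, samples in
#'   columns.  Dimnames supply `species_ids` / `sample_ids` when present.
#' @param cohort_labels One label per sample; defaults to a single cohort
#'   `"all"`.
#' @param species_ids,sample_ids Optional identifier vectors (unique).
#' @param normalize If `TRUE` (default), close columns to sum 1.
#' @return An object of class `abundance_table`.
#' @examples
#' m <- matrix(c(0.5, 0.3, 0.2, 0.9, 0.1, 0), nrow = 3)
#' abundance_table(m, cohort_labels = c("H", "D"))
#' @export
abundance_table <- function(abundances, cohort_labels = NULL,
                            species_ids = NULL, sample_ids = NULL,
                            normalize = TRUE) {
  abundances <- as.matrix(abundances)
  storage.mode(abundances) <- "double"
  if (anyNA(abundances)) stop_dglvr("abundances contain missing values")
  if (any(abundances < 0)) {
    bad <- which(abundances < 0, arr.ind = TRUE)[1, ]
    stop_dglvr("negative abundance at species %d, sample %d", bad[1], bad[2])
  }
  species_ids <- species_ids %||% rownames(abundances) %||%
    paste0("sp", seq_len(nrow(abundances)))
  sample_ids <- sample_ids %||% colnames(abundances) %||%
    paste0("sample", seq_len(ncol(abundances)))
  species_ids <- as.character(species_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(species_ids)) stop_dglvr("species_ids must be unique")
  if (anyDuplicated(sample_ids)) stop_dglvr("sample_ids must be unique")
  stopifnot(length(species_ids) == nrow(abundances),
            length(sample_ids) == ncol(abundances))

  totals <- colSums(abundances)
  if (any(totals == 0)) {
    stop_dglvr("empty sample (all-zero column): %s",
               paste(sample_ids[totals == 0], collapse = ", "))
  }
  if (normalize) {
    off <- abs(totals - 1) > 1e-6
    if (any(off)) {
      warning(sprintf("%d sample column(s) renormalized to sum to 1", sum(off)),
              call. = FALSE)
      abundances <- sweep(abundances, 2L, totals, `/`)
    }
  }
  cohort_labels <- cohort_labels %||% rep("all", ncol(abundances))
  cohort_labels <- as.character(cohort_labels)
  if (length(cohort_labels) != ncol(abundances)) {
    stop_dglvr("need one cohort label per sample (%d labels for %d samples)",
               length(cohort_labels), ncol(abundances))
  }
  dimnames(abundances) <- list(species_ids, sample_ids)
  structure(
    list(abundances = abundances, species_ids = species_ids,
         sample_ids = sample_ids, cohort_labels = cohort_labels),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table>\n")
  cat(sprintf("  %d species x %d samples\n", nrow(x$abundances), ncol(x$abundances)))
  tab <- table(x$cohort_labels)
  cat("  cohorts:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$abundances)

#' Long-format view of an abundance table
#'
#' @param x An `abundance_table`.
#' @param ... Unused.
#' @return A tibble with columns `species`, `sample`, `cohort`, `abundance`.
#' @export
as_tibble.abundance_table <- function(x, ...) {
  tibble::tibble(
    species = rep(x$species_ids, times = ncol(x$abundances)),
    sample = rep(x$sample_ids, each = nrow(x$abundances)),
    cohort = rep(x$cohort_labels, each = nrow(x$abundances)),
    abundance = as.vector(x$abundances)
  )
}

#' Coerce a long tibble to an abundance table
#'
#' @param x A data frame with columns `species`, `sample`, `abundance` and
#'   optionally `cohort`.
#' @param ... Passed to [abundance_table()].
#' @return An `abundance_table`.
#' @export
as_abundance_table <- function(x, ...) {
  if (inherits(x, "abundance_table")) return(x)
  stopifnot(is.data.frame(x), all(c("species", "sample", "abundance") %in% names(x)))
  wide <- tidyr::pivot_wider(x[, c("species", "sample", "abundance")],
                             names_from = "sample", values_from = "abundance",
                             values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$species
  labels <- NULL
  if ("cohort" %in% names(x)) {
    map <- dplyr::distinct(x[, c("sample", "cohort")])
    labels <- map$cohort[match(colnames(m), map$sample)]
  }
  abundance_table(m, cohort_labels = labels, ...)
}

#' Read an abundance table from TSV, CSV or BIOM
#'
#' Expects species in rows and samples in columns (header row of sample
#' identifiers, first column species identifiers) unless
#' `orientation = "samples_rows"`.  Cohort labels come from, in order of
#' precedence: the `metadata` sidecar (a file or data frame mapping
#' `sample_id` to a label column), a row labelled `cohort` inside the
#' table itself, or default to a single cohort.  Columns are renormalized
#' to sum to 1 (with a warning) when any total deviates by more than
#' `1e-6`, so count tables are accepted.
#'
#' @param path Path to the table.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"biom"`
#'   (requires the biomformat package).
#' @param orientation `"species_rows"` (default) or `"samples_rows"`.
#' @param metadata Optional sidecar: a path to a TSV/CSV or a data frame
#'   whose first column is the sample identifier.
#' @param cohort_col Name of the label column in `metadata` (default: the
#'   second column).
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path, format = c("auto", "tsv", "csv", "biom"),
                                 orientation = c("species_rows", "samples_rows"),
                                 metadata = NULL, cohort_col = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_dglvr("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", biom = "biom", "tsv")
  }

  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop_dglvr("reading BIOM requires the biomformat package")
    }
    bm <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(bm))   # species (observations) x samples
  } else {
    delim <- if (format == "csv") "," else "\t"
    df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop_dglvr("non-numeric abundance fields in %s", path)
    rownames(m) <- ids
    if (orientation == "samples_rows") m <- t(m)
  }

  labels <- NULL
  label_row <- tolower(rownames(m)) %in% c("cohort", "#cohort", "label")
  if (any(label_row)) {
    labels <- as.character(m[which(label_row)[1], ])
    m <- m[!label_row, , drop = FALSE]
  }
  if (!is.null(metadata)) {
    md <- if (is.data.frame(metadata)) {
      metadata
    } else {
      readr::read_delim(metadata,
                        delim = if (tolower(tools::file_ext(metadata)) == "csv") "," else "\t",
                        show_col_types = FALSE, progress = FALSE)
    }
    cohort_col <- cohort_col %||% names(md)[2]
    idx <- match(colnames(m), as.character(md[[1]]))
    if (anyNA(idx)) {
      stop_dglvr("metadata is missing labels for sample(s): %s",
                 paste(colnames(m)[is.na(idx)], collapse = ", "))
    }
    labels <- as.character(md[[cohort_col]][idx])
  }
  abundance_table(m, cohort_labels = labels)
}

#' Write an abundance table as TSV
#'
#' Species in rows, samples in columns, first column `species_id`; cohort
#' labels go to a sidecar `<path>.metadata.tsv` when present.
#'
#' @param x An `abundance_table`.
#' @param path Output path.
#' @param metadata_path Optional sidecar path (default `<path>.metadata.tsv`).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  df <- tibble::as_tibble(x$abundances, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(species_id = x$species_ids), df)
  readr::write_tsv(df, path)
  if (length(unique(x$cohort_labels)) > 1L || !all(x$cohort_labels == "all")) {
    metadata_path <- metadata_path %||% paste0(path, ".metadata.tsv")
    readr::write_tsv(tibble::tibble(sample_id = x$sample_ids,
                                    cohort = x$cohort_labels),
                     metadata_path)
  }
  invisible(path)
}

# Subset samples (columns) of an abundance table, keeping all species rows.
.subset_samples <- function(x, idx) {
  abundance_table(x$abundances[, idx, drop = FALSE],
                  cohort_labels = x$cohort_labels[idx],
                  species_ids = x$species_ids,
                  sample_ids = x$sample_ids[idx],
                  normalize = FALSE)
}
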