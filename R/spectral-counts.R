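#' Spectral-count matrix
#'
#' Container for label-free spectral counts: a proteins-by-samples matrix of
#' non-negative counts plus per-sample metadata. A protein absent from a
#' sample has count 0 (absence is zero evidence in spectral counting, not
#' missing-at-random).
#'
#' @param counts Numeric matrix, proteins in rows (rownames are protein
#'   ids), samples in columns (colnames are sample ids). All entries must be
#'   non-negative; raw matrices are integer counts, normalized matrices are
#'   reals.
#' @param samples Tibble with one row per column of `counts`, columns
#'   `sample_id`, `experiment`, `condition`, `replicate` and optionally
#'   `treatment_minutes` (metadata only).
#' @return An object of class `spectral_counts`.
#' @export
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 25L), 2, 2,
#'   dimnames = list(c("p1", "p2"), c("s1", "s2"))
#' )
#' s <- tibble::tibble(
#'   sample_id = c("s1", "s2"), experiment = "protoplast",
#'   condition = c("fermentation", "fe_reduction"), replicate = "R1"
#' )
#' spectral_counts(m, s)
spectral_counts <- function(counts, samples) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_bad_input("counts must be a matrix with protein rownames and sample colnames")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort_bad_input("counts must be finite and non-negative")
  }
  samples <- as_tibble(samples)
  needed <- c("sample_id", "experiment", "condition", "replicate")
  miss <- setdiff(needed, names(samples))
  if (length(miss) > 0L) {
    abort_bad_input(sprintf("samples is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!identical(colnames(counts), samples$sample_id)) {
    abort_bad_input("colnames(counts) must equal samples$sample_id, in order")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort_bad_input("sample ids must be unique")
  }
  key <- do.call(paste, c(samples[needed[-1]], list(samples[["treatment_minutes"]] %||% ""), sep = "\r"))
  if (anyDuplicated(key)) {
    abort_bad_input("sample metadata tuples (experiment, condition, replicate, treatment) must be unique")
  }
  structure(list(counts = counts, samples = samples), class = "spectral_counts")
}

#' @export
print.spectral_counts <- function(x, ...) {
  cat(sprintf(
    "<spectral_counts> %d proteins x %d samples (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(unique(x$samples$experiment), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.spectral_counts <- function(x) dim(x$counts)

#' Read and write spectral-count matrices
#'
#' The on-disk representation is two UTF-8 tab-separated files: a count
#' table whose first column is `protein_id` and remaining columns are
#' sample ids, and a sample-metadata table. A write/read round trip
#' reproduces the object field for field.
#'
#' @param counts_path,samples_path Paths of the two TSV files.
#' @return A [spectral_counts()] object.
#' @export
read_spectral_counts <- function(counts_path, samples_path) {
  ctab <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE, progress = FALSE)
  samples$replicate <- as.character(samples$replicate)
  if ("treatment_minutes" %in% names(samples)) {
    samples$treatment_minutes <- as.double(samples$treatment_minutes)
  }
  m <- as.matrix(ctab[, -1, drop = FALSE])
  rownames(m) <- ctab[[1]]
  spectral_counts(m, samples)
}

#' @rdname read_spectral_counts
#' @param x A `spectral_counts` object.
#' @export
write_spectral_counts <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "spectral_counts"))
  ctab <- bind_cols(
    tibble(protein_id = rownames(x$counts)),
    as_tibble(x$counts)
  )
  readr::write_tsv(ctab, counts_path, progress = FALSE)
  readr::write_tsv(x$samples, samples_path, progress = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Read and write dimethyl-label ratio tables
#'
#' A ratio table has one row per protein per labeling replicate with
#' columns `protein_id`, `log2_ratio` (finite), `intensity` (positive),
#' `comparison` (label of the condition pair) and `label_swapped` (whether
#' the isotope labels were applied in the reversed orientation for this
#' replicate).
#'
#' @param path Path to a tab-separated table with a header row.
#' @return A validated tibble.
#' @export
read_ratio_table <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      log2_ratio = readr::col_double(),
      intensity = readr::col_double(),
      comparison = readr::col_character(),
      label_swapped = readr::col_logical()
    ),
    progress = FALSE
  )
  validate_ratio_table(tab)
  tab
}

#' @rdname read_ratio_table
#' @param ratios Ratio tibble.
#' @export
write_ratio_table <- function(ratios, path) {
  validate_ratio_table(ratios)
  readr::write_tsv(ratios, path, progress = FALSE)
  invisible(path)
}

validate_ratio_table <- function(ratios) {
  miss <- setdiff(c("protein_id", "log2_ratio", "intensity"), names(ratios))
  if (length(miss) > 0L) {
    abort_bad_input(sprintf("ratio table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(ratios$log2_ratio))) {
    abort_bad_input("log2_ratio must be finite")
  }
  if (any(!is.finite(ratios$intensity) | ratios$intensity <= 0)) {
    abort_bad_input("intensity must be positive")
  }
  invisible(ratios)
}
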