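#' Read and write protein identification tables
#'
#' An identification table has one row per protein per sample with columns
#' `protein_id`, `experiment` (`protoplast`, `shaving` or `shedding`),
#' `condition` (`fermentation` or `fe_reduction`), `replicate`, `n_peptides`,
#' `protein_fdr` (fraction in \[0, 1\], may be missing) and `spectral_count`
#' (protoplast experiment only; missing means zero evidence and reads as 0).
#'
#' @param path Path to a tab-separated table with a header row.
#' @return A validated tibble.
#' @export
read_identifications <- function(path) {
  spec <- list(
    protein_id = readr::col_character(),
    experiment = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_character(),
    n_peptides = readr::col_integer(),
    protein_fdr = readr::col_double(),
    spectral_count = readr::col_integer()
  )
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  tab <- readr::read_tsv(
    path,
    col_types = do.call(readr::cols, spec[intersect(names(spec), header)]),
    progress = FALSE
  )
  validate_identifications(tab)
  tab
}

#' @rdname read_identifications
#' @param records Identification tibble as returned by
#'   [read_identifications()].
#' @export
write_identifications <- function(records, path) {
  validate_identifications(records)
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

validate_identifications <- function(records) {
  needed <- c("protein_id", "experiment", "condition", "replicate", "n_peptides")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0L) {
    abort_bad_input(sprintf(
      "identification table is missing column(s): %s", paste(miss, collapse = ", ")
    ))
  }
  if (any(records$n_peptides < 0, na.rm = TRUE)) {
    abort_bad_input("n_peptides must be >= 0")
  }
  if ("protein_fdr" %in% names(records)) {
    fdr <- records$protein_fdr
    if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) {
      abort_bad_input("protein_fdr must lie in [0, 1]")
    }
  }
  if ("spectral_count" %in% names(records) &&
      any(records$spectral_count < 0, na.rm = TRUE)) {
    abort_bad_input("spectral_count must be >= 0")
  }
  bad_exp <- setdiff(unique(records$experiment), c("protoplast", "shaving", "shedding"))
  if (length(bad_exp) > 0L) {
    abort_bad_input(sprintf("unknown experiment label(s): %s", paste(bad_exp, collapse = ", ")))
  }
  invisible(records)
}

#' Filter protein identifications
#'
#' Applies the identification-level quality filter: a protein is kept in a
#' sample when it was identified with at least `min_peptides` peptides and
#' its protein-level false-discovery rate, where reported, does not exceed
#' `max_protein_fdr`. The defaults (2 peptides, FDR 0.01) are the filter
#' applied throughout this workflow. Row order is preserved; the filter is
#' idempotent.
#'
#' @param records Identification tibble.
#' @param min_peptides Minimum peptides per protein (default 2).
#' @param max_protein_fdr Maximum protein-level FDR (default 0.01). Records
#'   with no FDR value are kept.
#' @return The filtered tibble, a subsequence of the input.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   protein_id = c("a", "b"), experiment = "protoplast",
#'   condition = "fermentation", replicate = "R1",
#'   n_peptides = c(1L, 3L), protein_fdr = c(0.005, 0.005)
#' )
#' filter_identifications(recs)
filter_identifications <- function(records, min_peptides = 2, max_protein_fdr = 0.01) {
  stopifnot(min_peptides >= 0, max_protein_fdr >= 0, max_protein_fdr <= 1)
  if (nrow(records) == 0L) {
    return(records)
  }
  keep <- records$n_peptides >= min_peptides
  if ("protein_fdr" %in% names(records)) {
    keep <- keep & (is.na(records$protein_fdr) | records$protein_fdr <= max_protein_fdr)
  }
  records[keep, , drop = FALSE]
}
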