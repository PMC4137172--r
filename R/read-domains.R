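#' Parse an hmmscan per-domain table
#'
#' Reads the whitespace-separated per-domain table written by
#' `hmmscan --domtblout` (comment lines start with `#`). In that dialect the
#' target is the profile HMM (the Pfam domain) and the query is the protein;
#' the independent e-value and the alignment coordinates on the protein are
#' taken from the standard column positions. Pfam accession version suffixes
#' are stripped so `PF01476.18` and `PF01476` compare equal.
#'
#' @param path Path to the per-domain table.
#' @return Tibble with columns `protein_id`, `accession`, `name`,
#'   `ali_start`, `ali_end`, `i_evalue`. A file of only comments yields a
#'   zero-row tibble.
#' @export
parse_domain_hits <- function(path) {
  if (!file.exists(path)) {
    abort_bad_input(sprintf("domain table does not exist: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) == 0L) {
    return(tibble(
      protein_id = character(), accession = character(), name = character(),
      ali_start = integer(), ali_end = integer(), i_evalue = double()
    ))
  }
  rows <- lapply(seq_along(data_lines), function(i) {
    f <- strsplit(trimws(data_lines[[i]]), "\\s+")[[1]]
    if (length(f) < 19L) {
      abort_bad_input(sprintf(
        "line %d of %s: expected >= 19 whitespace-separated fields, got %d",
        line_no[[i]], path, length(f)
      ))
    }
    i_eval <- suppressWarnings(as.numeric(f[[13]]))
    if (is.na(i_eval)) {
      abort_bad_input(sprintf(
        "line %d of %s: non-numeric independent e-value field '%s'",
        line_no[[i]], path, f[[13]]
      ))
    }
    list(
      protein_id = f[[4]],
      accession = sub("\\.[0-9]+$", "", f[[2]]),
      name = f[[1]],
      ali_start = as.integer(f[[18]]),
      ali_end = as.integer(f[[19]]),
      i_evalue = i_eval
    )
  })
  out <- tibble(
    protein_id = vapply(rows, `[[`, character(1), "protein_id"),
    accession = vapply(rows, `[[`, character(1), "accession"),
    name = vapply(rows, `[[`, character(1), "name"),
    ali_start = vapply(rows, `[[`, integer(1), "ali_start"),
    ali_end = vapply(rows, `[[`, integer(1), "ali_end"),
    i_evalue = vapply(rows, `[[`, double(1), "i_evalue")
  )
  bad <- out$ali_start > out$ali_end
  if (any(bad)) {
    abort_bad_input(sprintf(
      "alignment start > end for hit(s) on: %s",
      paste(out$protein_id[bad], collapse = ", ")
    ))
  }
  if (any(out$i_evalue < 0)) {
    abort_bad_input("negative independent e-value in domain table")
  }
  out
}
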