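#' Read a proteome FASTA file
#'
#' Reads amino-acid sequences via [Biostrings::readAAStringSet()] and returns
#' a validated tibble. The protein id is the first whitespace-delimited token
#' of each header; the remainder is kept as the description. Residues are
#' upper-cased; sequences must use the 20 standard amino-acid letters plus
#' `X`, and ids must be unique within the file.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`, `length`.
#'   An empty file yields a zero-row tibble with a warning.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">Dred_0462 ferredoxin", "MKT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort_bad_input(sprintf("FASTA file does not exist: %s", path))
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    warn(sprintf("FASTA file contains no records: %s", path))
    return(tibble(
      id = character(), description = character(),
      sequence = character(), length = integer()
    ))
  }
  header <- names(aa)
  id <- sub("\\s.*$", "", header)
  description <- ifelse(
    grepl("\\s", header),
    sub("^\\S+\\s+", "", header),
    ""
  )
  sequence <- toupper(as.character(aa))
  dup <- duplicated(id)
  if (any(dup)) {
    abort_bad_input(sprintf(
      "duplicate protein id(s) in %s: %s",
      path, paste(unique(id[dup]), collapse = ", ")
    ))
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)
  if (any(bad)) {
    abort_bad_input(sprintf(
      "sequence with non amino-acid characters in record(s): %s",
      paste(id[bad], collapse = ", ")
    ))
  }
  tibble(
    id = unname(id),
    description = unname(description),
    sequence = unname(sequence),
    length = nchar(sequence)
  )
}

#' Write protein entries as FASTA
#'
#' Inverse of [read_fasta()]: a write/read round trip reproduces the tibble
#' field for field.
#'
#' @param proteins Tibble with columns `id`, `description`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  desc <- proteins$description %||% rep("", nrow(proteins))
  header <- ifelse(desc == "" | is.na(desc), proteins$id, paste(proteins$id, desc))
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence, header))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
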