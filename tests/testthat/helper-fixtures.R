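# Small in-code fixture builders shared across test files.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

write_psortb_tmp <- function(ids, labels) {
  write_lines_tmp(c(
    "SeqID\tLocalization\tScore",
    paste(ids, labels, "9.97", sep = "\t")
  ), ext = ".tsv")
}

write_locatep_tmp <- function(ids, labels, lipoprotein = rep("no", length(ids))) {
  write_lines_tmp(c(
    "protein_id\tlocalization\tlipoprotein",
    paste(ids, labels, lipoprotein, sep = "\t")
  ), ext = ".tsv")
}

# one hmmscan per-domain table line (23 fields, i-Evalue in field 13,
# alignment coordinates in fields 18/19)
domtbl_line <- function(protein_id, accession, name = "dom",
                        ali_start = 10, ali_end = 50, i_evalue = 1e-10) {
  sprintf(
    "%s %s 120 %s - 400 %.2e 50.0 0.1 1 1 %.2e %.2e 48.0 0.1 1 40 %d %d %d %d 0.95 fixture",
    name, accession, protein_id, i_evalue, i_evalue, i_evalue,
    ali_start, ali_end, ali_start, ali_end
  )
}

make_counts <- function(m, conditions, experiment = "protoplast",
                        treatment = rep(NA_real_, ncol(m))) {
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("p%d", seq_len(nrow(m)))
  }
  spectral_counts(m, tibble::tibble(
    sample_id = colnames(m),
    experiment = experiment,
    condition = conditions,
    replicate = sprintf("R%d", seq_len(ncol(m))),
    treatment_minutes = treatment
  ))
}

# independent clause-by-clause evaluator of the differential-expression
# rule, used as the brute-force oracle
de_oracle <- function(mean_a, err_a, mean_b, err_b, fold_min = 2, abs_min = 5) {
  hi <- max(mean_a, mean_b)
  lo <- min(mean_a, mean_b)
  err_hi <- if (mean_a >= mean_b) err_a else err_b
  err_lo <- if (mean_a >= mean_b) err_b else err_a
  fold_ok <- if (lo == 0) hi > 0 else hi / lo >= fold_min
  abs_ok <- (hi - lo) >= abs_min
  sep_ok <- (hi - err_hi) > (lo + err_lo)
  if (fold_ok && abs_ok && sep_ok) {
    if (mean_a > mean_b) "up_in_A" else "up_in_B"
  } else {
    "none"
  }
}
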