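#' Classify the membrane anchor from transmembrane-helix topology
#'
#' Turns a protein's predicted helix topology into an anchor class:
#' no helix -> `NONE`; two or more helices -> `POLYTOPIC` (membrane
#' spanning); a single helix starting within `n_term_window` residues of the
#' N-terminus -> `N_TERMINAL_ANCHOR`; a single helix ending within
#' `c_term_window` residues of the C-terminus -> `C_TERMINAL_ANCHOR`; a
#' single helix elsewhere is assigned to the terminus whose half contains
#' its midpoint. The window defaults (35 and 40 residues) cover typical
#' signal-anchor and tail-anchor geometries and are configurable.
#'
#' @param n_helices Number of predicted transmembrane helices.
#' @param segments Two-column data frame (`start`, `end`) of helix
#'   coordinates, 1-based inclusive, sorted and non-overlapping.
#' @param protein_length Protein length in residues (>= 1).
#' @param n_term_window,c_term_window Terminal windows in residues.
#' @return One of [anchor_levels()].
#' @export
#' @examples
#' interpret_topology(1, data.frame(start = 98, end = 117), 120)
interpret_topology <- function(n_helices, segments, protein_length,
                               n_term_window = 35, c_term_window = 40) {
  stopifnot(protein_length >= 1)
  segments <- as.data.frame(segments)
  if (nrow(segments) != n_helices) {
    abort_bad_input("number of segments must equal n_helices")
  }
  if (n_helices == 0L) {
    return("NONE")
  }
  if (any(segments$start < 1 | segments$end > protein_length)) {
    abort_bad_input(sprintf(
      "helix segment outside [1, %d]", as.integer(protein_length)
    ))
  }
  if (any(segments$start > segments$end)) {
    abort_bad_input("helix segment with start > end")
  }
  if (n_helices >= 2L) {
    o <- order(segments$start)
    if (any(segments$start[o][-1] <= segments$end[o][-n_helices])) {
      abort_bad_input("helix segments overlap")
    }
    return("POLYTOPIC")
  }
  s <- segments$start[[1]]
  e <- segments$end[[1]]
  if (s <= n_term_window) {
    "N_TERMINAL_ANCHOR"
  } else if (e >= protein_length - c_term_window) {
    "C_TERMINAL_ANCHOR"
  } else if ((s + e) / 2 <= protein_length / 2) {
    "N_TERMINAL_ANCHOR"
  } else {
    "C_TERMINAL_ANCHOR"
  }
}

# vectorized over a topology tibble (as from parse_predictor_output)
anchors_from_topology <- function(topology, protein_lengths,
                                  n_term_window = 35, c_term_window = 40) {
  if (is.null(topology) || nrow(topology) == 0L) {
    return(tibble(protein_id = character(), anchor = character()))
  }
  len <- protein_lengths[topology$protein_id]
  if ("length" %in% names(topology)) {
    len <- ifelse(is.na(len), topology$length, len)
  }
  if (any(is.na(len))) {
    abort_bad_input(sprintf(
      "no protein length available for: %s",
      paste(topology$protein_id[is.na(len)], collapse = ", ")
    ))
  }
  anchor <- vapply(seq_len(nrow(topology)), function(i) {
    interpret_topology(
      topology$n_helices[[i]], topology$segments[[i]], len[[i]],
      n_term_window = n_term_window, c_term_window = c_term_window
    )
  }, character(1))
  tibble(protein_id = topology$protein_id, anchor = anchor)
}
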