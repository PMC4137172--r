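#' Consensus subcellular localization from per-tool calls
#'
#' Combines at most one canonical call per predictor tool into a single
#' compartment per protein, with a confidence grade. The rule, applied in
#' order (calls of `UNKNOWN` never count):
#'
#' 1. Two or more tools agree on a compartment: that compartment,
#'    confidence `consensus`.
#' 2. Exactly one informative call: if it is anything but `CYTOPLASM`,
#'    that compartment with confidence `evidence_tiebreak` (the single call
#'    is not contradicted and, for the membrane, is backed by the anchor);
#'    a lone `CYTOPLASM` call contradicted by a membrane anchor becomes
#'    `SURFACE_UNKNOWN`/`unresolved`, otherwise `CYTOPLASM`/`unresolved`.
#' 3. Mutually conflicting informative calls: if a `CYTOPLASM` call stands
#'    against membrane evidence (an anchor or a `CYTOPLASMIC_MEMBRANE`
#'    call), the protein is kept as `SURFACE_UNKNOWN`/`unresolved` — it is
#'    potentially membrane bound; conflicting non-cytoplasmic calls with no
#'    `CYTOPLASM` call also give `SURFACE_UNKNOWN` (the tools agree the
#'    protein is at the surface but not where); a `CYTOPLASM` call against
#'    a non-membrane surface call with no anchor is left `UNKNOWN`.
#' 4. No informative call: `UNKNOWN`/`unresolved`.
#'
#' The result is independent of the order in which tool calls are supplied,
#' and adding a call that agrees with the current compartment never lowers
#' the confidence. `is_surface` is true for every compartment except
#' `CYTOPLASM`, and for `UNKNOWN` only when a membrane anchor is present.
#'
#' @param calls Tibble of predictor calls with columns `protein_id`, `tool`
#'   and `canonical_label` (at most one row per protein and tool; two calls
#'   from the same tool are an error).
#' @param anchors Optional tibble (`protein_id`, `anchor`); proteins absent
#'   from it are taken to have anchor `NONE`.
#' @return Tibble with one row per protein: `protein_id`, `compartment`,
#'   `confidence` (`consensus`, `evidence_tiebreak` or `unresolved`),
#'   `anchor`, `is_surface`, and `supporting_tools` (comma-separated tools
#'   whose call equals the final compartment).
#' @export
consensus_localization <- function(calls, anchors = NULL) {
  stopifnot(all(c("protein_id", "tool", "canonical_label") %in% names(calls)))
  bad_tool <- setdiff(unique(calls$tool), .predictor_tools)
  if (length(bad_tool) > 0L) {
    abort_bad_input(sprintf("unknown tool(s) in calls: %s", paste(bad_tool, collapse = ", ")))
  }
  dup <- calls |>
    dplyr::count(.data$protein_id, .data$tool) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort_bad_input(sprintf(
      "more than one call from the same tool for: %s",
      paste(unique(dup$protein_id), collapse = ", ")
    ))
  }
  anchor_map <- character(0)
  if (!is.null(anchors) && nrow(anchors) > 0L) {
    anchor_map <- setNames(anchors$anchor, anchors$protein_id)
  }
  ids <- sort(unique(c(calls$protein_id, names(anchor_map))))
  split_calls <- split(calls, factor(calls$protein_id, levels = ids))
  rows <- lapply(ids, function(id) {
    a <- unname(anchor_map[id])
    if (is.na(a)) a <- "NONE"
    consensus_one(split_calls[[id]], a, id)
  })
  bind_rows(rows)
}

consensus_one <- function(prot_calls, anchor, protein_id) {
  labels <- character(0)
  tools <- character(0)
  if (!is.null(prot_calls) && nrow(prot_calls) > 0L) {
    o <- order(prot_calls$tool) # permutation invariance
    labels <- prot_calls$canonical_label[o]
    tools <- prot_calls$tool[o]
  }
  informative <- labels != "UNKNOWN"
  lab <- labels[informative]
  tl <- tools[informative]
  tab <- table(lab)
  membrane_evidence <- anchor != "NONE" || "CYTOPLASMIC_MEMBRANE" %in% lab

  if (length(tab) > 0L && max(tab) >= 2L) {
    compartment <- names(tab)[which.max(tab)]
    confidence <- "consensus"
  } else if (length(lab) == 1L) {
    if (lab == "CYTOPLASM") {
      if (anchor != "NONE") {
        compartment <- "SURFACE_UNKNOWN"
        confidence <- "unresolved"
      } else {
        compartment <- "CYTOPLASM"
        confidence <- "unresolved"
      }
    } else {
      compartment <- lab
      confidence <- "evidence_tiebreak"
    }
  } else if (length(lab) == 0L) {
    compartment <- "UNKNOWN"
    confidence <- "unresolved"
  } else {
    # conflicting single calls
    if ("CYTOPLASM" %in% lab && membrane_evidence) {
      compartment <- "SURFACE_UNKNOWN"
    } else if (!"CYTOPLASM" %in% lab) {
      compartment <- "SURFACE_UNKNOWN"
    } else {
      compartment <- "UNKNOWN"
    }
    confidence <- "unresolved"
  }
  supporting <- tl[lab == compartment]
  is_surface <- (compartment != "CYTOPLASM" && compartment != "UNKNOWN") ||
    (compartment == "UNKNOWN" && anchor != "NONE")
  tibble(
    protein_id = protein_id,
    compartment = compartment,
    confidence = confidence,
    anchor = anchor,
    is_surface = is_surface,
    supporting_tools = paste(sort(supporting), collapse = ",")
  )
}

#' Annotate a proteome's surfaceome
#'
#' End-to-end per-protein annotation: derives the membrane anchor from the
#' helix topology, the consensus compartment from the predictor calls
#' ([consensus_localization()]), and the binding mechanism from domain hits
#' plus lipoprotein/LPxTG flags ([assign_binding_mechanism()]).
#'
#' @param proteins Tibble from [read_fasta()] (`id`, `length` used).
#' @param calls Predictor calls (rows from [parse_predictor_output()] for
#'   any subset of tools, bound together). Optional flag columns
#'   `lipoprotein` and `lpxtg` are honoured.
#' @param topology Topology tibble from the transmembrane scan, or `NULL`.
#' @param domains Domain-hit tibble from [parse_domain_hits()], or `NULL`.
#' @param n_term_window,c_term_window Passed to [interpret_topology()].
#' @param evalue_cutoff Passed to [assign_binding_mechanism()].
#' @return Tibble with one row per protein in `proteins`: `protein_id`,
#'   `compartment`, `confidence`, `anchor`, `binding`, `is_surface`,
#'   `supporting_tools`.
#' @export
annotate_surfaceome <- function(proteins, calls, topology = NULL, domains = NULL,
                                n_term_window = 35, c_term_window = 40,
                                evalue_cutoff = 1e-5) {
  stopifnot(all(c("id", "length") %in% names(proteins)))
  lens <- setNames(proteins$length, proteins$id)
  anchors <- anchors_from_topology(topology, lens,
    n_term_window = n_term_window, c_term_window = c_term_window
  )
  cons <- consensus_localization(calls, anchors)
  cons <- cons[cons$protein_id %in% proteins$id, , drop = FALSE]
  base <- tibble(protein_id = proteins$id) |>
    left_join(cons, by = "protein_id")
  base$compartment[is.na(base$compartment)] <- "UNKNOWN"
  base$confidence[is.na(base$confidence)] <- "unresolved"
  base$anchor[is.na(base$anchor)] <- "NONE"
  base$is_surface[is.na(base$is_surface)] <- FALSE
  base$supporting_tools[is.na(base$supporting_tools)] <- ""

  flags <- tibble(protein_id = proteins$id, lipoprotein = FALSE, lpxtg = FALSE)
  if (!is.null(calls) && nrow(calls) > 0L) {
    if (!"lipoprotein" %in% names(calls)) calls$lipoprotein <- FALSE
    if (!"lpxtg" %in% names(calls)) calls$lpxtg <- FALSE
    fl <- calls |>
      group_by(.data$protein_id) |>
      summarise(
        lipo = any(.data$lipoprotein, na.rm = TRUE),
        lpx = any(.data$lpxtg, na.rm = TRUE),
        .groups = "drop"
      )
    flags <- flags |>
      left_join(fl, by = "protein_id") |>
      mutate(
        lipoprotein = dplyr::coalesce(.data$lipo, FALSE),
        lpxtg = dplyr::coalesce(.data$lpx, FALSE)
      ) |>
      select("protein_id", "lipoprotein", "lpxtg")
  }
  dom_split <- NULL
  if (!is.null(domains) && nrow(domains) > 0L) {
    dom_split <- split(domains, domains$protein_id)
  }
  binding <- vapply(seq_len(nrow(base)), function(i) {
    id <- base$protein_id[[i]]
    assign_binding_mechanism(
      domains = if (is.null(dom_split)) NULL else dom_split[[id]],
      lipoprotein = flags$lipoprotein[[i]],
      lpxtg = flags$lpxtg[[i]],
      anchor = base$anchor[[i]],
      evalue_cutoff = evalue_cutoff
    )
  }, character(1))
  base$binding <- binding
  base[, c(
    "protein_id", "compartment", "confidence", "anchor", "binding",
    "is_surface", "supporting_tools"
  )]
}

#' Split an annotated proteome into surface and cytoplasmic sets
#'
#' @param annotations Annotation tibble from [annotate_surfaceome()] (or any
#'   tibble with `protein_id` and `is_surface`), one row per protein.
#' @return List with elements `surface` and `cytoplasm`, tibbles that
#'   partition the input.
#' @export
partition_surfaceome <- function(annotations) {
  stopifnot(all(c("protein_id", "is_surface") %in% names(annotations)))
  if (anyDuplicated(annotations$protein_id)) {
    abort_bad_input("annotations must have one row per protein")
  }
  list(
    surface = annotations[annotations$is_surface, , drop = FALSE],
    cytoplasm = annotations[!annotations$is_surface, , drop = FALSE]
  )
}

#' Write a surfaceome annotation table
#'
#' @param annotations Annotation tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}
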