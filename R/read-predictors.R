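#' Parse localization-predictor output
#'
#' Reads the output of one of the three supported localization predictors
#' and returns one canonicalized call per protein. Three dialects are
#' supported:
#'
#' * `TMH_SCAN` — the one-line transmembrane-helix scan format: one
#'   whitespace-separated record per protein with `key=value` fields,
#'   including the predicted helix count (`PredHel=`) and a topology string
#'   (`Topology=i98-117o`). The topology string is expanded into helix
#'   segments (1-based, inclusive coordinates) and the side of the
#'   N-terminus. A protein with at least one predicted helix yields a
#'   `CYTOPLASMIC_MEMBRANE` call, otherwise `UNKNOWN` (the scan carries no
#'   information about soluble proteins).
#' * `PSORTB` — tab-separated with a header row; the protein id is the
#'   first column and the localization is taken from the first column whose
#'   name contains "localization" (case-insensitive), so both the long and
#'   the short output variants are accepted.
#' * `LOCATEP` — tab-separated like `PSORTB`; an optional column whose name
#'   contains "lipoprotein" sets the lipoprotein flag (values `yes`/`no`,
#'   `TRUE`/`FALSE` or `1`/`0`).
#'
#' Raw labels are preserved verbatim; canonical compartments come from
#' [canonicalize_label()]. The `secreted` flag is set when the canonical
#' compartment is `EXTRACELLULAR` or the raw label mentions secretion; the
#' `lpxtg` flag when the raw label mentions an LPxTG anchor (reported by
#' LocateP-style tools).
#'
#' @param path Path to the predictor output.
#' @param tool One of [predictor_tools()].
#' @return For `PSORTB`/`LOCATEP`: a tibble of calls with columns
#'   `protein_id`, `tool`, `raw_label`, `canonical_label`, `lipoprotein`,
#'   `secreted`, `lpxtg`. For `TMH_SCAN`: a list with elements `calls` (same
#'   shape) and `topology` (tibble `protein_id`, `length`, `n_helices`,
#'   `n_term_side`, and list-column `segments` of two-column `start`/`end`
#'   tibbles).
#' @export
parse_predictor_output <- function(path, tool) {
  if (!is.character(tool) || length(tool) != 1L ||
      !toupper(tool) %in% .predictor_tools) {
    abort_bad_input(sprintf(
      "unknown tool '%s'; expected one of %s",
      paste(as.character(tool), collapse = ","),
      paste(.predictor_tools, collapse = ", ")
    ))
  }
  tool <- toupper(tool)
  if (!file.exists(path)) {
    abort_bad_input(sprintf("predictor file does not exist: %s", path))
  }
  switch(tool,
    TMH_SCAN = parse_tmh_scan(path),
    PSORTB = parse_loc_table(path, "PSORTB"),
    LOCATEP = parse_loc_table(path, "LOCATEP")
  )
}

parse_tmh_scan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  recs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    id <- fields[[1]]
    kv <- fields[grepl("=", fields, fixed = TRUE)]
    keys <- tolower(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    get <- function(k) if (k %in% keys) vals[[match(k, keys)]] else NA_character_
    pred_hel <- suppressWarnings(as.integer(get("predhel")))
    if (is.na(pred_hel)) {
      abort_bad_input(sprintf("line %d of %s: missing or non-integer PredHel field", i, path))
    }
    topo <- get("topology")
    len <- suppressWarnings(as.integer(get("len")))
    seg <- expand_topology(topo)
    if (nrow(seg$segments) != pred_hel) {
      abort_bad_input(sprintf(
        "line %d of %s: PredHel=%d but topology string encodes %d segment(s)",
        i, path, pred_hel, nrow(seg$segments)
      ))
    }
    list(
      id = id, raw = if (is.na(topo)) sprintf("PredHel=%d", pred_hel) else
        sprintf("PredHel=%d Topology=%s", pred_hel, topo),
      n_helices = pred_hel, length = len,
      n_term_side = seg$n_term_side, segments = seg$segments
    )
  })
  ids <- vapply(recs, `[[`, character(1), "id")
  n_hel <- vapply(recs, `[[`, integer(1), "n_helices")
  topology <- tibble(
    protein_id = ids,
    length = vapply(recs, `[[`, integer(1), "length"),
    n_helices = n_hel,
    n_term_side = vapply(recs, `[[`, character(1), "n_term_side"),
    segments = lapply(recs, `[[`, "segments")
  )
  calls <- tibble(
    protein_id = ids,
    tool = "TMH_SCAN",
    raw_label = vapply(recs, `[[`, character(1), "raw"),
    canonical_label = ifelse(n_hel >= 1L, "CYTOPLASMIC_MEMBRANE", "UNKNOWN"),
    lipoprotein = FALSE,
    secreted = FALSE,
    lpxtg = FALSE
  )
  list(calls = calls, topology = topology)
}

# "i98-117o" -> N-terminus inside, one helix 98..117
expand_topology <- function(topo) {
  if (is.na(topo) || topo == "") {
    return(list(
      n_term_side = "unknown",
      segments = tibble(start = integer(), end = integer())
    ))
  }
  first <- substr(topo, 1, 1)
  side <- switch(first, i = "in", o = "out", "unknown")
  m <- gregexpr("([0-9]+)-([0-9]+)", topo)[[1]]
  if (m[1] == -1) {
    segments <- tibble(start = integer(), end = integer())
  } else {
    pieces <- regmatches(topo, gregexpr("([0-9]+)-([0-9]+)", topo))[[1]]
    start <- as.integer(sub("-.*$", "", pieces))
    end <- as.integer(sub("^.*-", "", pieces))
    segments <- tibble(start = start, end = end)
  }
  list(n_term_side = side, segments = segments)
}

parse_loc_table <- function(path, tool) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2L) {
    abort_bad_input(sprintf("%s table %s needs at least two columns", tool, path))
  }
  loc_col <- grep("localization", names(tab), ignore.case = TRUE, value = TRUE)
  if (length(loc_col) == 0L) {
    abort_bad_input(sprintf("%s table %s has no localization column", tool, path))
  }
  loc_col <- loc_col[[1]]
  raw <- as.character(tab[[loc_col]])
  missing_loc <- which(is.na(raw) | raw == "")
  if (length(missing_loc) > 0L) {
    abort_bad_input(sprintf(
      "%s table %s: missing localization on data line(s) %s",
      tool, path, paste(missing_loc, collapse = ", ")
    ))
  }
  lipo <- rep(FALSE, nrow(tab))
  if (tool == "LOCATEP") {
    lipo_col <- grep("lipoprotein", names(tab), ignore.case = TRUE, value = TRUE)
    if (length(lipo_col) > 0L) {
      v <- tolower(as.character(tab[[lipo_col[[1]]]]))
      lipo <- v %in% c("yes", "true", "1")
    }
    lipo <- lipo | grepl("lipid", raw, ignore.case = TRUE)
  }
  canonical <- canonicalize_label(tool, raw)
  tibble(
    protein_id = as.character(tab[[1]]),
    tool = tool,
    raw_label = raw,
    canonical_label = canonical,
    lipoprotein = lipo,
    secreted = canonical == "EXTRACELLULAR" | grepl("secret", raw, ignore.case = TRUE),
    lpxtg = grepl("lpxtg", raw, ignore.case = TRUE)
  )
}
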