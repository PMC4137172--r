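#' Cross-experiment membership tally
#'
#' Set arithmetic over the proteins identified in two extraction
#' experiments (e.g. protoplast formation vs cell shaving/shedding): totals
#' per experiment, counts unique to each, the shared count, and the split
#' of every row into surface and cytoplasmic proteins. By construction
#' `total = unique + shared` for each experiment and
#' `total = surface + cytoplasm` within every row; the tally is invariant
#' to input order and duplicate ids are ignored.
#'
#' @param sets Named list of two character vectors of protein ids, one per
#'   experiment.
#' @param surface Character vector: the surface set (subset of the union of
#'   `sets`).
#' @return Tibble with columns `group` (`total`, `unique`, `shared`),
#'   `experiment`, `total`, `surface`, `cytoplasm`.
#' @export
#' @examples
#' membership_tally(
#'   list(P = c("a", "b", "c"), Sh = c("b", "c", "d")),
#'   surface = c("b", "d")
#' )
membership_tally <- function(sets, surface = character(0)) {
  if (!is.list(sets) || length(sets) != 2L || is.null(names(sets)) ||
      any(names(sets) == "")) {
    abort_bad_input("sets must be a named list of two protein-id vectors")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  surface <- unique(as.character(surface))
  universe <- union(sets[[1]], sets[[2]])
  stray <- setdiff(surface, universe)
  if (length(stray) > 0L) {
    abort_bad_input(sprintf(
      "surface set contains ids absent from both experiments: %s",
      paste(head(stray, 5), collapse = ", ")
    ))
  }
  shared <- intersect(sets[[1]], sets[[2]])
  pieces <- list(
    list(group = "total", experiment = names(sets)[[1]], ids = sets[[1]]),
    list(group = "total", experiment = names(sets)[[2]], ids = sets[[2]]),
    list(group = "unique", experiment = names(sets)[[1]], ids = setdiff(sets[[1]], sets[[2]])),
    list(group = "unique", experiment = names(sets)[[2]], ids = setdiff(sets[[2]], sets[[1]])),
    list(group = "shared", experiment = paste(names(sets), collapse = "&"), ids = shared)
  )
  bind_rows(lapply(pieces, function(p) {
    n_surface <- length(intersect(p$ids, surface))
    tibble(
      group = p$group, experiment = p$experiment,
      total = length(p$ids), surface = n_surface,
      cytoplasm = length(p$ids) - n_surface
    )
  }))
}

#' Default function-category rule table
#'
#' Ordered first-match-wins rules assigning each surface protein to one of
#' five broad functional categories from its description and domain
#' content: transport (ABC and TRAP transporters, permeases, solute
#' binding), chemotaxis and motility (methyl-accepting chemotaxis proteins,
#' flagellar and pilus components), proteases and cell-wall hydrolases
#' (including the cell-wall-hydrolase-associated copper amine oxidase
#' N-terminal domain PF07833 and penicillin-binding proteins), redox
#' (ferredoxins, reductases, oxidoreductases, 4Fe-4S proteins), and a
#' catch-all other/unknown. The table is plain data: edit or replace it to
#' change the categorisation without touching code. A copy is shipped as
#' `extdata/function_rules.tsv`.
#'
#' @return Tibble with columns `kind` (`keyword` matched against the
#'   description, case-insensitively, or `accession` matched against domain
#'   accessions), `pattern` and `category`.
#' @export
default_function_rules <- function() {
  tibble::tribble(
    ~kind, ~pattern, ~category,
    "keyword", "methyl-accepting chemotaxis", "CHEMOTAXIS",
    "keyword", "chemotaxis", "CHEMOTAXIS",
    "keyword", "flagell", "CHEMOTAXIS",
    "keyword", "pilus", "CHEMOTAXIS",
    "keyword", "pilin", "CHEMOTAXIS",
    "keyword", "ABC transporter", "TRANSPORT",
    "keyword", "TRAP", "TRANSPORT",
    "keyword", "transporter", "TRANSPORT",
    "keyword", "permease", "TRANSPORT",
    "keyword", "symporter", "TRANSPORT",
    "keyword", "antiporter", "TRANSPORT",
    "keyword", "solute binding", "TRANSPORT",
    "keyword", "substrate binding", "TRANSPORT",
    "keyword", "efflux", "TRANSPORT",
    "keyword", "secretion", "TRANSPORT",
    "keyword", "peptidase", "PROTEASE_CW_HYDROLASE",
    "keyword", "protease", "PROTEASE_CW_HYDROLASE",
    "keyword", "hydrolase", "PROTEASE_CW_HYDROLASE",
    "keyword", "penicillin-binding", "PROTEASE_CW_HYDROLASE",
    "accession", "PF07833", "PROTEASE_CW_HYDROLASE",
    "keyword", "ferredoxin", "REDOX",
    "keyword", "oxidoreductase", "REDOX",
    "keyword", "reductase", "REDOX",
    "keyword", "hydrogenase", "REDOX",
    "keyword", "4Fe-4S", "REDOX"
  )
}

#' Function categories
#'
#' @return The five functional categories used in the surfaceome report.
#' @export
function_categories <- function() {
  c("TRANSPORT", "CHEMOTAXIS", "PROTEASE_CW_HYDROLASE", "REDOX", "OTHER_UNKNOWN")
}

#' Assign a functional category to each protein
#'
#' Applies an ordered rule table ([default_function_rules()] by default):
#' the first rule whose keyword matches the protein description
#' (case-insensitive, fixed string) or whose accession matches a domain hit
#' wins; proteins matching no rule fall into `OTHER_UNKNOWN`.
#'
#' @param proteins Tibble with columns `id` and `description`.
#' @param domains Optional domain-hit tibble (`protein_id`, `accession`).
#' @param rules Rule table with columns `kind`, `pattern`, `category`.
#' @return Tibble `protein_id`, `category`.
#' @export
#' @examples
#' categorize_function(tibble::tibble(
#'   id = "x", description = "methyl-accepting chemotaxis protein"
#' ))
categorize_function <- function(proteins, domains = NULL,
                                rules = default_function_rules()) {
  stopifnot(all(c("id", "description") %in% names(proteins)))
  if (!is.data.frame(rules) ||
      !all(c("kind", "pattern", "category") %in% names(rules)) ||
      !all(rules$kind %in% c("keyword", "accession")) ||
      !all(rules$category %in% function_categories())) {
    abort_bad_input("malformed rule table: need kind in {keyword, accession}, pattern, category")
  }
  dom_acc <- if (is.null(domains) || nrow(domains) == 0L) {
    list()
  } else {
    split(domains$accession, domains$protein_id)
  }
  category <- vapply(seq_len(nrow(proteins)), function(i) {
    desc <- tolower(proteins$description[[i]] %||% "")
    acc <- dom_acc[[proteins$id[[i]]]] %||% character(0)
    for (j in seq_len(nrow(rules))) {
      hit <- if (rules$kind[[j]] == "keyword") {
        grepl(tolower(rules$pattern[[j]]), desc, fixed = TRUE)
      } else {
        rules$pattern[[j]] %in% acc
      }
      if (hit) {
        return(rules$category[[j]])
      }
    }
    "OTHER_UNKNOWN"
  }, character(1))
  tibble(protein_id = proteins$id, category = category)
}

#' Function-by-localization-by-membership cross-tabulation
#'
#' Builds the surfaceome summary table: for each of the five function
#' categories, the protein count, its split over cellular localizations
#' (surface-unknown, cytoplasmic membrane, cell wall, extracellular, plus
#' unknown), over experiment membership (only in the first experiment, only
#' in the second, or both), and over differential-expression classes.
#' Every axis of the cross-tabulation sums to the number of surface
#' proteins; a protein present in one input but missing from another is an
#' error listing the ids.
#'
#' @param annotations Annotation tibble for the surface universe
#'   (`protein_id`, `compartment`).
#' @param categories Tibble `protein_id`, `category` from
#'   [categorize_function()].
#' @param sets Named list of two experiment protein-id sets (the membership
#'   universe; see [membership_tally()]).
#' @param de_calls Optional tibble `protein_id`, `direction` (`up_in_A`,
#'   `up_in_B`, `none`); proteins without a call count as `none`... they
#'   must still be present in the table if it is supplied.
#' @return Tibble with one row per function category plus a `TOTAL` row
#'   and columns for counts, localization, membership and differential
#'   expression.
#' @export
crosstab_surfaceome <- function(annotations, categories, sets, de_calls = NULL) {
  ids <- annotations$protein_id
  if (anyDuplicated(ids)) {
    abort_bad_input("annotations must have one row per protein")
  }
  check_universe <- function(other_ids, what) {
    missing_ids <- setdiff(ids, other_ids)
    extra <- setdiff(other_ids, ids)
    if (length(missing_ids) > 0L || length(extra) > 0L) {
      abort_bad_input(sprintf(
        "%s does not cover the same protein universe (missing: %s; extra: %s)",
        what,
        paste(head(missing_ids, 5), collapse = ", ") %||% "",
        paste(head(extra, 5), collapse = ", ") %||% ""
      ))
    }
  }
  check_universe(categories$protein_id, "categories")
  in_universe <- ids %in% union(sets[[1]], sets[[2]])
  if (!all(in_universe)) {
    abort_bad_input(sprintf(
      "protein(s) absent from both experiment sets: %s",
      paste(head(ids[!in_universe], 5), collapse = ", ")
    ))
  }
  if (!is.null(de_calls)) {
    check_universe(de_calls$protein_id, "de_calls")
  }

  membership <- ifelse(
    ids %in% sets[[1]] & ids %in% sets[[2]], "both",
    ifelse(ids %in% sets[[1]], paste0("only_", names(sets)[[1]]),
      paste0("only_", names(sets)[[2]])
    )
  )
  de <- rep("none", length(ids))
  if (!is.null(de_calls)) {
    de <- de_calls$direction[match(ids, de_calls$protein_id)]
    de[is.na(de)] <- "none"
  }
  cat_map <- categories$category[match(ids, categories$protein_id)]

  df <- tibble(
    category = factor(cat_map, levels = function_categories()),
    compartment = factor(annotations$compartment, levels = .compartments),
    membership = factor(membership, levels = c(
      paste0("only_", names(sets)[[1]]), paste0("only_", names(sets)[[2]]), "both"
    )),
    de = factor(de, levels = c("up_in_A", "up_in_B", "none"))
  )
  one_axis <- function(f, prefix) {
    t <- table(df$category, f)
    out <- as_tibble(unclass(as.matrix(t)), .name_repair = "minimal")
    names(out) <- paste0(prefix, colnames(t))
    out
  }
  res <- bind_cols(
    tibble(
      category = function_categories(),
      n = as.integer(table(df$category))
    ),
    one_axis(df$compartment, "loc_"),
    one_axis(df$membership, "mem_"),
    one_axis(df$de, "de_")
  )
  totals <- res |>
    summarise(across(-"category", sum)) |>
    mutate(category = "TOTAL")
  bind_rows(res, totals[, names(res)])
}
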