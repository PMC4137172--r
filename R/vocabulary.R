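# Controlled vocabularies shared across the package.

.compartments <- c(
  "CYTOPLASM", "CYTOPLASMIC_MEMBRANE", "CELL_WALL", "EXTRACELLULAR",
  "SURFACE_UNKNOWN", "UNKNOWN"
)

.truth_compartments <- .compartments[1:4]

.anchor_classes <- c("NONE", "N_TERMINAL_ANCHOR", "C_TERMINAL_ANCHOR", "POLYTOPIC")

.binding_mechanisms <- c(
  "LPXTG", "SLH", "LYSM", "CWBD1", "CWBD2", "GW",
  "LIPID_ANCHOR", "TMH_ANCHOR", "NONE"
)

.predictor_tools <- c("TMH_SCAN", "PSORTB", "LOCATEP")

#' Controlled vocabularies
#'
#' Levels used throughout the package. `compartment_levels()` returns the
#' canonical subcellular compartments (`SURFACE_UNKNOWN` means "not
#' cytoplasmic, compartment undetermined"); `anchor_levels()` the membrane
#' anchor classes derived from transmembrane-helix topology;
#' `binding_levels()` the surface-binding mechanisms in priority order
#' (covalent LPxTG wall anchoring first, no mechanism last);
#' `predictor_tools()` the supported localization predictors.
#'
#' @return A character vector of levels.
#' @export
#' @examples
#' compartment_levels()
compartment_levels <- function() .compartments

#' @rdname compartment_levels
#' @export
anchor_levels <- function() .anchor_classes

#' @rdname compartment_levels
#' @export
binding_levels <- function() .binding_mechanisms

#' @rdname compartment_levels
#' @export
predictor_tools <- function() .predictor_tools

#' Pfam accessions of the recognised cell-wall binding domains
#'
#' The non-covalent cell-wall binding domains looked up when classifying a
#' protein's surface-binding mechanism: S-layer homology (SLH, PF00395),
#' LysM (PF01476), choline-binding CWBD1 (PF01473), CWBD2 (PF04122) and
#' glycine-tryptophan GW modules (PF13457). Accessions are version-free;
#' [parse_domain_hits()] strips version suffixes so they compare equal.
#'
#' @return Named character vector, names are binding-mechanism levels.
#' @export
#' @examples
#' binding_domain_accessions()
binding_domain_accessions <- function() {
  c(
    SLH   = "PF00395",
    LYSM  = "PF01476",
    CWBD1 = "PF01473",
    CWBD2 = "PF04122",
    GW    = "PF13457"
  )
}

#' Map a predictor's localization label onto the canonical compartments
#'
#' Localization predictors use tool-specific vocabularies ("Cytoplasmic",
#' "CytoplasmicMembrane", "Lipid anchored", ...). This maps each raw label
#' deterministically onto [compartment_levels()]. Matching is insensitive to
#' case, whitespace and punctuation; labels not covered by the shipped table
#' fall through a small set of keyword rules (LPxTG -> cell wall, anchored /
#' transmembrane / membrane -> cytoplasmic membrane, secreted / released ->
#' extracellular, non-cytoplasmic -> surface-unknown) and anything still
#' unmatched maps to `UNKNOWN` with a warning.
#'
#' A predictor that can rule out the cytoplasm without naming a compartment
#' ("Non-cytoplasmic") maps to the distinct value `SURFACE_UNKNOWN`, which
#' downstream consensus treats as real (non-cytoplasmic) evidence.
#'
#' @param tool Predictor name, one of [predictor_tools()] (recorded, and used
#'   in the warning for unmapped labels).
#' @param raw_label Character vector of labels as printed by the tool.
#' @return Character vector of canonical compartments, same length as
#'   `raw_label`.
#' @export
#' @examples
#' canonicalize_label("PSORTB", c("CytoplasmicMembrane", "Unknown"))
canonicalize_label <- function(tool, raw_label) {
  tool <- match.arg(toupper(tool), .predictor_tools)
  stopifnot(is.character(raw_label))
  key <- normalize_label_key(raw_label)
  out <- unname(.label_map[key])
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- fallback_label(key[miss])
    still <- miss & is.na(out)
    if (any(still)) {
      warn(sprintf(
        "%s label(s) not in the localization vocabulary, mapped to UNKNOWN: %s",
        tool, paste(unique(raw_label[still]), collapse = ", ")
      ))
      out[still] <- "UNKNOWN"
    }
  }
  out
}

normalize_label_key <- function(x) {
  tolower(gsub("[^a-z0-9]", "", tolower(x)))
}

# exact lookup table, keys pre-normalized
.label_map <- c(
  cytoplasm                = "CYTOPLASM",
  cytoplasmic              = "CYTOPLASM",
  intracellular            = "CYTOPLASM",
  cytoplasmicmembrane      = "CYTOPLASMIC_MEMBRANE",
  membrane                 = "CYTOPLASMIC_MEMBRANE",
  plasmamembrane           = "CYTOPLASMIC_MEMBRANE",
  lipidanchored            = "CYTOPLASMIC_MEMBRANE",
  multitransmembrane       = "CYTOPLASMIC_MEMBRANE",
  cellwall                 = "CELL_WALL",
  lpxtgcellwallanchored    = "CELL_WALL",
  extracellular            = "EXTRACELLULAR",
  secreted                 = "EXTRACELLULAR",
  secretory                = "EXTRACELLULAR",
  secretoryreleased        = "EXTRACELLULAR",
  unknown                  = "UNKNOWN",
  unknownmayhavemultiplelocalizationsites = "UNKNOWN",
  noncytoplasmic           = "SURFACE_UNKNOWN"
)

fallback_label <- function(key) {
  out <- rep(NA_character_, length(key))
  out[grepl("lpxtg", key)] <- "CELL_WALL"
  hit <- is.na(out) & grepl("cellwall", key)
  out[hit] <- "CELL_WALL"
  hit <- is.na(out) & grepl("noncytoplasmic", key)
  out[hit] <- "SURFACE_UNKNOWN"
  hit <- is.na(out) & (grepl("anchor", key) | grepl("transmembrane", key) | grepl("membrane", key))
  out[hit] <- "CYTOPLASMIC_MEMBRANE"
  hit <- is.na(out) & (grepl("secret", key) | grepl("released", key) | grepl("extracellular", key))
  out[hit] <- "EXTRACELLULAR"
  out
}
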