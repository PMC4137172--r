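#' Classify a protein's surface-binding mechanism
#'
#' Picks exactly one binding mechanism per protein by a fixed priority:
#' a covalent LPxTG wall anchor (flagged by LocateP-style predictors) beats
#' any non-covalent cell-wall binding domain; among domains the order is
#' SLH (PF00395) > LysM (PF01476) > CWBD1 (PF01473) > CWBD2 (PF04122) > GW
#' (PF13457), considering only hits at or below the independent e-value
#' cutoff; failing those, a lipoprotein flag gives `LIPID_ANCHOR`, a
#' membrane anchor gives `TMH_ANCHOR`, and otherwise `NONE`.
#'
#' @param domains Tibble of domain hits for one protein (columns
#'   `accession`, `i_evalue`), or `NULL`.
#' @param lipoprotein Logical: predicted lipoprotein.
#' @param lpxtg Logical: LPxTG wall anchor reported.
#' @param anchor Anchor class from [interpret_topology()].
#' @param evalue_cutoff Maximum independent e-value for a domain hit to
#'   count (default 1e-5).
#' @return One of [binding_levels()].
#' @export
#' @examples
#' assign_binding_mechanism(
#'   tibble::tibble(accession = "PF01476", i_evalue = 1e-10),
#'   lipoprotein = FALSE, lpxtg = FALSE, anchor = "NONE"
#' )
assign_binding_mechanism <- function(domains = NULL, lipoprotein = FALSE,
                                     lpxtg = FALSE, anchor = "NONE",
                                     evalue_cutoff = 1e-5) {
  stopifnot(evalue_cutoff > 0)
  anchor <- match.arg(anchor, .anchor_classes)
  if (isTRUE(lpxtg)) {
    return("LPXTG")
  }
  if (!is.null(domains) && nrow(domains) > 0L) {
    acc <- domains$accession[domains$i_evalue <= evalue_cutoff]
    wall <- binding_domain_accessions()
    for (mech in c("SLH", "LYSM", "CWBD1", "CWBD2", "GW")) {
      if (wall[[mech]] %in% acc) {
        return(mech)
      }
    }
  }
  if (isTRUE(lipoprotein)) {
    return("LIPID_ANCHOR")
  }
  if (anchor != "NONE") {
    return("TMH_ANCHOR")
  }
  "NONE"
}
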