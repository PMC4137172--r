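test_that("label canonicalization follows the fixed mapping with an UNKNOWN fallback", {
  expect_equal(canonicalize_label("PSORTB", "CytoplasmicMembrane"), "CYTOPLASMIC_MEMBRANE")
  expect_equal(canonicalize_label("LOCATEP", "Cytoplasmic"), "CYTOPLASM")
  expect_equal(canonicalize_label("PSORTB", "Cellwall"), "CELL_WALL")
  expect_equal(canonicalize_label("PSORTB", "Extracellular"), "EXTRACELLULAR")
  expect_equal(canonicalize_label("LOCATEP", "Secreted"), "EXTRACELLULAR")
  expect_equal(canonicalize_label("PSORTB", "Unknown"), "UNKNOWN")
  expect_equal(
    canonicalize_label("PSORTB", "Unknown (may have multiple localization sites)"),
    "UNKNOWN"
  )
  expect_equal(canonicalize_label("PSORTB", "Non-cytoplasmic"), "SURFACE_UNKNOWN")
  expect_equal(canonicalize_label("LOCATEP", "LPxTG cell wall anchored"), "CELL_WALL")
  expect_equal(canonicalize_label("LOCATEP", "N-terminally anchored (No CS)"), "CYTOPLASMIC_MEMBRANE")
  expect_warning(
    out <- canonicalize_label("PSORTB", "banana"),
    "banana"
  )
  expect_equal(out, "UNKNOWN")
})

test_that("topology interpretation distinguishes terminal anchors and polytopic proteins", {
  # single helix near the C-terminus of a 120-residue protein
  expect_equal(
    interpret_topology(1, data.frame(start = 98, end = 117), 120),
    "C_TERMINAL_ANCHOR"
  )
  # single helix at the N-terminus
  expect_equal(
    interpret_topology(1, data.frame(start = 5, end = 27), 300),
    "N_TERMINAL_ANCHOR"
  )
  # five membrane-spanning segments
  segs <- data.frame(start = c(10, 50, 90, 130, 170), end = c(30, 70, 110, 150, 190))
  expect_equal(interpret_topology(5, segs, 220), "POLYTOPIC")
  expect_equal(interpret_topology(0, data.frame(start = integer(), end = integer()), 100), "NONE")
  # mid-protein helix falls back to the midpoint rule
  expect_equal(
    interpret_topology(1, data.frame(start = 100, end = 120), 300),
    "N_TERMINAL_ANCHOR"
  )
  expect_equal(
    interpret_topology(1, data.frame(start = 160, end = 180), 300),
    "C_TERMINAL_ANCHOR"
  )
})

test_that("topology interpretation rejects out-of-range and overlapping segments", {
  expect_error(interpret_topology(1, data.frame(start = 98, end = 130), 120), "outside")
  expect_error(
    interpret_topology(2, data.frame(start = c(10, 20), end = c(25, 40)), 100),
    "overlap"
  )
})

test_that("binding mechanism follows the priority order", {
  lysm <- tibble::tibble(accession = "PF01476", i_evalue = 1e-10)
  expect_equal(assign_binding_mechanism(lysm), "LYSM")
  # LPxTG beats any wall domain; SLH beats LysM
  expect_equal(assign_binding_mechanism(lysm, lpxtg = TRUE), "LPXTG")
  both <- tibble::tibble(accession = c("PF01476", "PF00395"), i_evalue = c(1e-10, 1e-9))
  expect_equal(assign_binding_mechanism(both), "SLH")
  # hits above the e-value cutoff do not count
  weak <- tibble::tibble(accession = "PF01476", i_evalue = 1e-3)
  expect_equal(assign_binding_mechanism(weak, lipoprotein = TRUE), "LIPID_ANCHOR")
  expect_equal(assign_binding_mechanism(NULL, lipoprotein = TRUE), "LIPID_ANCHOR")
  expect_equal(assign_binding_mechanism(NULL, anchor = "POLYTOPIC"), "TMH_ANCHOR")
  expect_equal(assign_binding_mechanism(NULL), "NONE")
  # the truncated misprint of the S-layer accession is not a wall domain
  misprint <- tibble::tibble(accession = "PF0039", i_evalue = 1e-12)
  expect_equal(assign_binding_mechanism(misprint), "NONE")
})

test_that("consensus follows two-of-three agreement with evidence tie-breaks", {
  mk <- function(labels, anchor = "NONE") {
    calls <- tibble::tibble(
      protein_id = "p",
      tool = c("TMH_SCAN", "PSORTB", "LOCATEP")[seq_along(labels)],
      canonical_label = labels
    )
    consensus_localization(calls, tibble::tibble(protein_id = "p", anchor = anchor))
  }
  # unanimity -> consensus, excluded from the surfaceome
  out <- mk(c("CYTOPLASM", "CYTOPLASM", "CYTOPLASM"))
  expect_equal(out$compartment, "CYTOPLASM")
  expect_equal(out$confidence, "consensus")
  expect_false(out$is_surface)

  # helix-derived membrane call + PSORTb membrane, LocateP uninformative
  out <- mk(c("CYTOPLASMIC_MEMBRANE", "CYTOPLASMIC_MEMBRANE", "UNKNOWN"),
    anchor = "C_TERMINAL_ANCHOR"
  )
  expect_equal(out$compartment, "CYTOPLASMIC_MEMBRANE")
  expect_equal(out$confidence, "consensus")
  expect_equal(out$supporting_tools, "PSORTB,TMH_SCAN")

  # membrane evidence against a cytoplasm call: kept, but unresolved
  calls <- tibble::tibble(
    protein_id = "p", tool = c("TMH_SCAN", "LOCATEP", "PSORTB"),
    canonical_label = c("CYTOPLASMIC_MEMBRANE", "CYTOPLASM", "UNKNOWN")
  )
  out <- consensus_localization(
    calls, tibble::tibble(protein_id = "p", anchor = "N_TERMINAL_ANCHOR")
  )
  expect_equal(out$compartment, "SURFACE_UNKNOWN")
  expect_equal(out$confidence, "unresolved")
  expect_true(out$is_surface)

  # a single informative non-cytoplasmic call wins a tie-break
  out <- mk(c("UNKNOWN", "CELL_WALL", "UNKNOWN"))
  expect_equal(out$compartment, "CELL_WALL")
  expect_equal(out$confidence, "evidence_tiebreak")

  # a lone cytoplasm call with a membrane anchor is contradicted
  out <- mk(c("UNKNOWN", "CYTOPLASM", "UNKNOWN"), anchor = "POLYTOPIC")
  expect_equal(out$compartment, "SURFACE_UNKNOWN")
  # ... without the anchor it stands, unresolved
  out <- mk(c("UNKNOWN", "CYTOPLASM", "UNKNOWN"))
  expect_equal(out$compartment, "CYTOPLASM")
  expect_equal(out$confidence, "unresolved")

  # nothing informative
  out <- mk(c("UNKNOWN", "UNKNOWN", "UNKNOWN"))
  expect_equal(out$compartment, "UNKNOWN")
  expect_false(out$is_surface)
  out <- mk(c("UNKNOWN", "UNKNOWN", "UNKNOWN"), anchor = "POLYTOPIC")
  expect_true(out$is_surface)
})

test_that("consensus is invariant to call order and monotone in agreement", {
  labels <- c("CYTOPLASM", "CYTOPLASMIC_MEMBRANE", "CELL_WALL", "EXTRACELLULAR", "SURFACE_UNKNOWN", "UNKNOWN")
  set.seed(42)
  conf_rank <- c(unresolved = 0, evidence_tiebreak = 1, consensus = 2)
  for (i in 1:40) {
    tools <- sample(c("TMH_SCAN", "PSORTB", "LOCATEP"), sample(1:3, 1))
    labs <- sample(labels, length(tools), replace = TRUE)
    anchor <- sample(anchor_levels(), 1)
    calls <- tibble::tibble(protein_id = "p", tool = tools, canonical_label = labs)
    anchors <- tibble::tibble(protein_id = "p", anchor = anchor)
    ref <- consensus_localization(calls, anchors)
    perm <- consensus_localization(calls[sample(nrow(calls)), ], anchors)
    expect_equal(perm, ref)
    # adding an agreeing call from an unused tool never lowers confidence
    free <- setdiff(c("TMH_SCAN", "PSORTB", "LOCATEP"), tools)
    if (length(free) > 0 && ref$compartment != "UNKNOWN") {
      more <- dplyr::bind_rows(calls, tibble::tibble(
        protein_id = "p", tool = free[[1]], canonical_label = ref$compartment
      ))
      out2 <- consensus_localization(more, anchors)
      expect_gte(conf_rank[[out2$confidence]], conf_rank[[ref$confidence]])
      expect_equal(out2$compartment, ref$compartment)
    }
  }
})

test_that("two calls from one tool are rejected", {
  calls <- tibble::tibble(
    protein_id = "p", tool = c("PSORTB", "PSORTB"),
    canonical_label = c("CYTOPLASM", "CELL_WALL")
  )
  expect_error(consensus_localization(calls), "same tool")
})

test_that("partition splits annotations exactly and handles empty input", {
  ann <- tibble::tibble(
    protein_id = sprintf("p%d", 1:10),
    is_surface = c(rep(FALSE, 4), rep(TRUE, 6))
  )
  parts <- partition_surfaceome(ann)
  expect_equal(nrow(parts$surface), 6L)
  expect_equal(nrow(parts$cytoplasm), 4L)
  expect_setequal(
    c(parts$surface$protein_id, parts$cytoplasm$protein_id), ann$protein_id
  )
  empty <- partition_surfaceome(ann[0, ])
  expect_equal(nrow(empty$surface), 0L)
  expect_equal(nrow(empty$cytoplasm), 0L)
})

test_that("annotate_surfaceome integrates calls, topology, domains and flags", {
  proteins <- tibble::tibble(
    id = c("mem", "wall", "lipo"),
    description = "",
    sequence = strrep("M", 10),
    length = c(120L, 300L, 200L)
  )
  calls <- dplyr::bind_rows(
    tibble::tibble(
      protein_id = "mem", tool = c("TMH_SCAN", "PSORTB"),
      canonical_label = "CYTOPLASMIC_MEMBRANE",
      lipoprotein = FALSE, lpxtg = FALSE
    ),
    tibble::tibble(
      protein_id = "wall", tool = c("PSORTB", "LOCATEP"),
      canonical_label = "CELL_WALL", lipoprotein = FALSE, lpxtg = FALSE
    ),
    tibble::tibble(
      protein_id = "lipo", tool = c("PSORTB", "LOCATEP"),
      canonical_label = "EXTRACELLULAR", lipoprotein = c(FALSE, TRUE), lpxtg = FALSE
    )
  )
  topology <- tibble::tibble(
    protein_id = "mem", length = 120L, n_helices = 1L, n_term_side = "in",
    segments = list(tibble::tibble(start = 98L, end = 117L))
  )
  domains <- tibble::tibble(
    protein_id = "wall", accession = "PF01476", name = "LysM",
    ali_start = 10L, ali_end = 52L, i_evalue = 1e-12
  )
  ann <- annotate_surfaceome(proteins, calls, topology, domains)
  expect_equal(ann$protein_id, proteins$id)
  expect_equal(ann$compartment, c("CYTOPLASMIC_MEMBRANE", "CELL_WALL", "EXTRACELLULAR"))
  expect_equal(ann$anchor, c("C_TERMINAL_ANCHOR", "NONE", "NONE"))
  expect_equal(ann$binding, c("TMH_ANCHOR", "LYSM", "LIPID_ANCHOR"))
  expect_true(all(ann$is_surface))
})
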