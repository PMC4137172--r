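test_that("read_fasta parses records, ids and lengths", {
  fa <- write_lines_tmp(c(">Dred_0462 ferredoxin", "MKT"), ext = ".fasta")
  out <- read_fasta(fa)
  expect_equal(nrow(out), 1L)
  expect_equal(out$id, "Dred_0462")
  expect_equal(out$description, "ferredoxin")
  expect_equal(out$length, 3L)
})

test_that("read_fasta rejects duplicate ids and foreign characters", {
  fa <- write_lines_tmp(c(">a", "MKT", ">a", "MV"), ext = ".fasta")
  expect_error(read_fasta(fa), "duplicate")
  fa2 <- write_lines_tmp(c(">b descr", "MK*T"), ext = ".fasta")
  expect_error(read_fasta(fa2), "b")
})

test_that("read_fasta warns on an empty file and returns zero rows", {
  fa <- write_lines_tmp(character(0), ext = ".fasta")
  expect_warning(out <- read_fasta(fa), "no records")
  expect_equal(nrow(out), 0L)
})

test_that("lowercase residues are upper-cased and survive a write/read round trip", {
  fa <- write_lines_tmp(c(">x some protein", "mkvl", ">y", "MMMM"), ext = ".fasta")
  first <- read_fasta(fa)
  expect_equal(first$sequence[[1]], "MKVL")
  expect_equal(first$length[[1]], 4L)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(first, out)
  expect_equal(read_fasta(out), first)
})

test_that("the one-line transmembrane-scan dialect is decoded", {
  f <- write_lines_tmp(paste0(
    "Dred_0462\tlen=120\tExpAA=20.93\tFirst60=0.01\t",
    "PredHel=1\tTopology=i98-117o"
  ))
  out <- parse_predictor_output(f, "TMH_SCAN")
  expect_equal(out$topology$n_helices, 1L)
  expect_equal(out$topology$n_term_side, "in")
  expect_equal(out$topology$segments[[1]]$start, 98L)
  expect_equal(out$topology$segments[[1]]$end, 117L)
  expect_equal(out$calls$canonical_label, "CYTOPLASMIC_MEMBRANE")

  # no helix: topology string is just the side; the call is uninformative
  f0 <- write_lines_tmp("p0\tlen=90\tExpAA=0.1\tFirst60=0.1\tPredHel=0\tTopology=o")
  out0 <- parse_predictor_output(f0, "TMH_SCAN")
  expect_equal(out0$topology$n_helices, 0L)
  expect_equal(nrow(out0$topology$segments[[1]]), 0L)
  expect_equal(out0$calls$canonical_label, "UNKNOWN")

  # multi-helix strings expand to all segments
  fm <- write_lines_tmp("pm\tlen=200\tExpAA=63\tFirst60=20\tPredHel=3\tTopology=i7-29o44-66i101-123o")
  outm <- parse_predictor_output(fm, "TMH_SCAN")
  expect_equal(outm$topology$segments[[1]]$start, c(7L, 44L, 101L))
})

test_that("table dialects yield one canonical call per row", {
  f <- write_psortb_tmp(c("a", "b", "c"), c("CytoplasmicMembrane", "Unknown", "Cytoplasmic"))
  out <- parse_predictor_output(f, "PSORTB")
  expect_equal(nrow(out), 3L)
  expect_equal(out$canonical_label, c("CYTOPLASMIC_MEMBRANE", "UNKNOWN", "CYTOPLASM"))
  expect_equal(out$raw_label[[1]], "CytoplasmicMembrane")

  fl <- write_locatep_tmp(c("a", "b"), c("Lipid anchored", "Secretory (released)"),
    lipoprotein = c("yes", "no")
  )
  outl <- parse_predictor_output(fl, "LOCATEP")
  expect_equal(outl$canonical_label, c("CYTOPLASMIC_MEMBRANE", "EXTRACELLULAR"))
  expect_equal(outl$lipoprotein, c(TRUE, FALSE))
  expect_true(outl$secreted[[2]])
})

test_that("predictor parsing fails on unknown tools and missing localization", {
  f <- write_psortb_tmp("a", "Cytoplasmic")
  expect_error(parse_predictor_output(f, "SIGNALP"), "unknown tool")
  bad <- write_lines_tmp(c("SeqID\tScore", "a\t1.0"), ext = ".tsv")
  expect_error(parse_predictor_output(bad, "PSORTB"), "localization")
  gap <- write_lines_tmp(c("SeqID\tLocalization", "a\tCytoplasmic", "b\t"), ext = ".tsv")
  expect_error(parse_predictor_output(gap, "PSORTB"), "line")
})

test_that("domain-table parsing strips accession versions and keeps coordinates", {
  f <- write_lines_tmp(c(
    "# comment",
    domtbl_line("protA", "PF01476.18", name = "LysM", ali_start = 12, ali_end = 55),
    domtbl_line("protB", "PF00395", name = "SLH", ali_start = 3, ali_end = 44, i_evalue = 2e-8),
    domtbl_line("protC", "PF99999", name = "DUF", ali_start = 100, ali_end = 160, i_evalue = 1e-3)
  ))
  out <- parse_domain_hits(f)
  expect_equal(nrow(out), 3L)
  expect_equal(out$accession, c("PF01476", "PF00395", "PF99999"))
  expect_equal(out$ali_start, c(12L, 3L, 100L))
  expect_equal(out$ali_end, c(55L, 44L, 160L))
  expect_equal(out$i_evalue[[2]], 2e-8, tolerance = 0.01)
})

test_that("comment-only domain tables are empty; bad e-values are named", {
  f <- write_lines_tmp(c("# only", "# comments"))
  expect_equal(nrow(parse_domain_hits(f)), 0L)
  bad <- write_lines_tmp(gsub("1.00e-10", "oops", domtbl_line("p", "PF00001"), fixed = TRUE))
  expect_error(parse_domain_hits(bad), "line 1")
})

test_that("identification filter keeps two peptides at FDR 0.01 and is idempotent", {
  recs <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    experiment = "protoplast", condition = "fermentation", replicate = "R1",
    n_peptides = c(1L, 3L, 2L, 5L),
    protein_fdr = c(0.001, 0.005, NA, 0.02)
  )
  kept <- filter_identifications(recs)
  expect_equal(kept$protein_id, c("b", "c"))

  # vacuous thresholds pass everything through unchanged
  expect_equal(filter_identifications(recs, min_peptides = 0, max_protein_fdr = 1), recs)
  # subsequence + idempotence
  expect_true(all(kept$protein_id %in% recs$protein_id))
  expect_equal(filter_identifications(kept), kept)
  expect_equal(nrow(filter_identifications(recs[0, ])), 0L)
})

test_that("identification, count and ratio tables round-trip through TSV", {
  recs <- tibble::tibble(
    protein_id = c("a", "b"), experiment = c("protoplast", "shaving"),
    condition = "fermentation", replicate = "R1",
    n_peptides = c(2L, 4L), protein_fdr = c(0.002, NA)
  )
  p <- withr::local_tempfile(fileext = ".tsv")
  write_identifications(recs, p)
  expect_equal(read_identifications(p), recs)

  m <- matrix(c(10, 0, 5, 25, 1, 7), 3, 2,
    dimnames = list(c("p1", "p2", "p3"), c("s1", "s2"))
  )
  x <- make_counts(m, c("fermentation", "fe_reduction"))
  cp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_spectral_counts(x, cp, sp)
  back <- read_spectral_counts(cp, sp)
  expect_equal(back$counts, x$counts)
  expect_equal(back$samples, x$samples)

  ratios <- tibble::tibble(
    protein_id = c("p1", "p1"), log2_ratio = c(0.5, -0.4),
    intensity = c(1e6, 1e6), comparison = "fe_vs_ferm",
    label_swapped = c(FALSE, TRUE)
  )
  rp <- withr::local_tempfile(fileext = ".tsv")
  write_ratio_table(ratios, rp)
  expect_equal(read_ratio_table(rp), ratios)
})

test_that("count and ratio containers enforce their invariants", {
  m <- matrix(-1, 1, 1, dimnames = list("p", "s"))
  expect_error(
    spectral_counts(m, tibble::tibble(
      sample_id = "s", experiment = "protoplast",
      condition = "fermentation", replicate = "R1"
    )),
    "non-negative"
  )
  expect_error(
    write_ratio_table(
      tibble::tibble(protein_id = "p", log2_ratio = 0, intensity = 0),
      withr::local_tempfile(fileext = ".tsv")
    ),
    "positive"
  )
})
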