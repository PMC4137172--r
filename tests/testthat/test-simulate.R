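test_that("generator configuration validates its probability inputs", {
  expect_error(
    generator_config(compartment_proportions = c(
      CYTOPLASM = 0.6, CYTOPLASMIC_MEMBRANE = 0.3,
      CELL_WALL = 0.05, EXTRACELLULAR = 0.1
    )),
    "sum to 1"
  )
  bad_conf <- default_tool_confusion()
  bad_conf$PSORTB[1, 1] <- 0.5
  expect_error(generator_config(tool_confusion = bad_conf), "probability")
  expect_error(
    generator_config(
      n_proteins = 10,
      spike_set = tibble::tibble(protein = 11, fold = 4, up_in = "fe_reduction")
    ),
    "outside"
  )
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- generator_config(n_proteins = 120, seed = 99)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$calls, b$calls)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$ratios, b$ratios)
  expect_identical(a$truth, b$truth)
  # materialised inputs are byte-identical too
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_synthetic_inputs(a, d1)
  p2 <- write_synthetic_inputs(b, d2)
  for (k in names(p1)) {
    expect_identical(
      unname(tools::md5sum(p1[[k]])), unname(tools::md5sum(p2[[k]])),
      label = k
    )
  }
  # a different seed changes the draw
  c2 <- simulate_study(generator_config(n_proteins = 120, seed = 100))
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("compartment truth frequencies follow the configured proportions", {
  cfg <- generator_config(
    n_proteins = 1000,
    compartment_proportions = c(
      CYTOPLASM = 0.4, CYTOPLASMIC_MEMBRANE = 0.4,
      CELL_WALL = 0.08, EXTRACELLULAR = 0.12
    ),
    seed = 21
  )
  truth <- generate_annotation_inputs(cfg)$truth
  n_cyto <- sum(truth$compartment == "CYTOPLASM")
  # 99% binomial interval around 400
  interval <- qbinom(c(0.005, 0.995), 1000, 0.4)
  expect_gte(n_cyto, interval[[1]])
  expect_lte(n_cyto, interval[[2]])
})

test_that("identity confusion matrices make every call equal the truth", {
  cfg <- generator_config(
    n_proteins = 250, tool_confusion = identity_confusion(), seed = 13
  )
  sim <- generate_annotation_inputs(cfg)
  truth_map <- setNames(sim$truth$compartment, sim$truth$protein_id)
  expect_true(all(sim$calls$canonical_label == truth_map[sim$calls$protein_id]))
  # membrane-truth proteins carry at least one helix
  mem <- sim$truth$protein_id[sim$truth$compartment == "CYTOPLASMIC_MEMBRANE"]
  topo <- sim$topology[match(mem, sim$topology$protein_id), ]
  expect_true(all(topo$n_helices >= 1L))
})

test_that("cell-wall binding domains are planted on cell-wall proteins", {
  cfg <- generator_config(
    n_proteins = 600, cw_domain_prob = 1, seed = 31
  )
  sim <- generate_annotation_inputs(cfg)
  cw <- sim$truth$protein_id[sim$truth$compartment == "CELL_WALL"]
  wall_hits <- sim$domains[sim$domains$accession %in% binding_domain_accessions(), ]
  expect_setequal(unique(wall_hits$protein_id), cw)
  expect_true(all(wall_hits$i_evalue <= 1e-5))
})

test_that("zero lysis contamination keeps cytoplasmic proteins out of the extracts", {
  cfg <- generator_config(n_proteins = 300, lysis_contamination_rate = 0, seed = 17)
  sim <- simulate_study(cfg)
  cyto <- !sim$truth$is_surface
  expect_true(all(sim$counts$counts[cyto, ] == 0))
  expect_false(any(sim$truth$contaminant_protoplast[cyto]))
  # with the default rate, contaminants do appear
  sim2 <- simulate_study(generator_config(n_proteins = 300, seed = 17))
  cyto2 <- !sim2$truth$is_surface
  expect_gt(sum(sim2$counts$counts[cyto2, ]), 0)
})

test_that("noise-free spikes show the exact configured fold and get called", {
  cfg <- generator_config(
    n_proteins = 100,
    lysis_contamination_rate = 0,
    detection_rate = c(protoplast = 1, shaving = 1),
    count_model = list(mean_log = log(20), sd_log = 0, dispersion = 8, noise = "none"),
    spike_set = tibble::tibble(protein = 1:2, fold = 4, up_in = c("fe_reduction", "fermentation")),
    seed = 8
  )
  sim <- simulate_study(cfg)
  surf <- sim$truth$is_surface
  spiked_id <- sim$truth$protein_id[1:2]
  m <- sim$counts$counts
  samp <- sim$counts$samples
  proto_fe <- samp$sample_id[samp$experiment == "protoplast" & samp$condition == "fe_reduction"]
  proto_ferm <- samp$sample_id[samp$experiment == "protoplast" & samp$condition == "fermentation"]
  if (surf[[1]]) {
    expect_equal(unname(rowMeans(m[spiked_id[[1]], proto_fe, drop = FALSE])), 80)
    expect_equal(unname(rowMeans(m[spiked_id[[1]], proto_ferm, drop = FALSE])), 20)
  }
  proto <- spectral_counts(m[surf, samp$experiment == "protoplast"], samp[samp$experiment == "protoplast", ])
  de <- spectral_de(proto)
  called <- de$protein_id[de$direction != "none"]
  expect_setequal(called, intersect(spiked_id, de$protein_id))
})

test_that("label-swapped ratio rows mirror their forward rows", {
  cfg <- generator_config(
    n_proteins = 150,
    ratio_noise = list(scale = 0, mean_log_intensity = log(1e6), sd_log_intensity = 1),
    seed = 23
  )
  sim <- simulate_study(cfg)
  fwd <- sim$ratios[!sim$ratios$label_swapped, ]
  rev <- sim$ratios[sim$ratios$label_swapped, ]
  expect_equal(rev$protein_id, fwd$protein_id)
  # at zero noise the mean of (forward, -swapped) equals the true log fold
  truth_fold <- setNames(
    log2(sim$truth$true_fold) *
      ifelse(sim$truth$de_status == "fermentation", -1, 1),
    sim$truth$protein_id
  )
  expect_equal((fwd$log2_ratio - rev$log2_ratio) / 2,
    unname(truth_fold[fwd$protein_id]),
    tolerance = 1e-12
  )
})
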