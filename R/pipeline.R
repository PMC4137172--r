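#' Run the full surfaceome-determination pipeline
#'
#' Orchestrates an end-to-end run: simulate a ground-truthed study (or read
#' previously written inputs), parse every input file through the package
#' readers, annotate the surfaceome, apply the identification filter, call
#' differential expression on the protoplast spectral counts, score the
#' shaving/shedding ratio table with significance B, and build the
#' membership tally and the function-by-localization cross-tabulation.
#' Outputs are written as TSV files plus a JSON run manifest recording the
#' package version, the seed and all thresholds; a run is byte-identical
#' for an identical configuration and seed.
#'
#' Stages fail loudly: a missing input file aborts with a diagnostic naming
#' the path, and the outputs of a failed stage are retained with a
#' `.partial` suffix.
#'
#' @param output_dir Directory for inputs (when simulating) and outputs.
#' @param config A [generator_config()] describing the simulated study, or
#'   `NULL` to reuse input files already present under
#'   `file.path(output_dir, "inputs")`.
#' @param min_peptides,max_protein_fdr Identification filter thresholds.
#' @param fold_min,abs_min Differential-expression rule thresholds.
#' @param bin_size Significance-B intensity bin size.
#' @param evalue_cutoff Domain e-value cutoff for binding classification.
#' @return Invisibly, a list with the output `paths`, the in-memory result
#'   tables and a `summary` of headline counts.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(tempfile(), config = generator_config(n_proteins = 200))
#' out$summary
#' }
run_pipeline <- function(output_dir,
                         config = generator_config(),
                         min_peptides = 2, max_protein_fdr = 0.01,
                         fold_min = 2, abs_min = 5,
                         bin_size = 300, evalue_cutoff = 1e-5) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  input_dir <- file.path(output_dir, "inputs")

  if (!is.null(config)) {
    stopifnot(inherits(config, "generator_config"))
    run_stage("simulate", character(0), {
      sim <- simulate_study(config)
      write_synthetic_inputs(sim, input_dir)
    })
  }
  inputs <- c(
    proteome = file.path(input_dir, "proteome.fasta"),
    tmh_scan = file.path(input_dir, "tmh_scan.txt"),
    psortb = file.path(input_dir, "psortb.tsv"),
    locatep = file.path(input_dir, "locatep.tsv"),
    domains = file.path(input_dir, "domains.domtbl"),
    identifications = file.path(input_dir, "identifications.tsv"),
    counts = file.path(input_dir, "spectral_counts.tsv"),
    samples = file.path(input_dir, "samples.tsv"),
    ratios = file.path(input_dir, "ratios.tsv")
  )
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0L) {
    abort_bad_input(sprintf(
      "missing input file(s): %s", paste(missing_in, collapse = ", ")
    ))
  }
  paths <- c(
    annotations = file.path(output_dir, "annotations.tsv"),
    de_calls = file.path(output_dir, "de_calls.tsv"),
    significance_b = file.path(output_dir, "significance_b.tsv"),
    table1 = file.path(output_dir, "table1.tsv"),
    table2 = file.path(output_dir, "table2.tsv"),
    manifest = file.path(output_dir, "manifest.json")
  )

  # classify
  ann_env <- new.env()
  run_stage("classify", paths[["annotations"]], {
    proteins <- read_fasta(inputs[["proteome"]])
    tmh <- parse_predictor_output(inputs[["tmh_scan"]], "TMH_SCAN")
    calls <- bind_rows(
      tmh$calls,
      parse_predictor_output(inputs[["psortb"]], "PSORTB"),
      parse_predictor_output(inputs[["locatep"]], "LOCATEP")
    )
    domains <- parse_domain_hits(inputs[["domains"]])
    annotations <- annotate_surfaceome(
      proteins, calls, tmh$topology, domains,
      evalue_cutoff = evalue_cutoff
    )
    write_annotations(annotations, paths[["annotations"]])
    assign("proteins", proteins, ann_env)
    assign("domains", domains, ann_env)
    assign("annotations", annotations, ann_env)
    message(sprintf(
      "stage=classify proteins=%d surface=%d",
      nrow(proteins), sum(annotations$is_surface)
    ))
  })
  proteins <- ann_env$proteins
  annotations <- ann_env$annotations

  # quantify
  q_env <- new.env()
  run_stage("quantify", paths[c("de_calls", "significance_b")], {
    ident <- read_identifications(inputs[["identifications"]])
    kept <- filter_identifications(ident, min_peptides, max_protein_fdr)
    scm <- read_spectral_counts(inputs[["counts"]], inputs[["samples"]])
    proto_cols <- scm$samples$experiment == "protoplast"
    proto <- spectral_counts(
      scm$counts[, proto_cols, drop = FALSE],
      scm$samples[proto_cols, , drop = FALSE]
    )
    de <- spectral_de(
      proto,
      condition_a = "fermentation", condition_b = "fe_reduction",
      error_mode_a = "semi_difference", error_mode_b = "sd",
      fold_min = fold_min, abs_min = abs_min
    )
    readr::write_tsv(de, paths[["de_calls"]], progress = FALSE)
    ratios <- read_ratio_table(inputs[["ratios"]])
    sigb <- significance_b(ratios, bin_size = bin_size)
    readr::write_tsv(sigb, paths[["significance_b"]], progress = FALSE)
    assign("kept", kept, q_env)
    assign("de", de, q_env)
    assign("sigb", sigb, q_env)
    message(sprintf(
      "stage=quantify identifications=%d kept=%d de_called=%d",
      nrow(ident), nrow(kept), sum(de$direction != "none")
    ))
  })

  # compare
  c_env <- new.env()
  run_stage("compare", paths[c("table1", "table2")], {
    kept <- q_env$kept
    sets <- list(
      P = unique(kept$protein_id[kept$experiment == "protoplast"]),
      Sh = unique(kept$protein_id[kept$experiment == "shaving"])
    )
    universe <- union(sets$P, sets$Sh)
    surface_ids <- annotations$protein_id[annotations$is_surface]
    tally <- membership_tally(sets, intersect(surface_ids, universe))
    readr::write_tsv(tally, paths[["table1"]], progress = FALSE)

    surf <- intersect(surface_ids, universe)
    ann_surf <- annotations[match(surf, annotations$protein_id), , drop = FALSE]
    cats <- categorize_function(
      proteins[match(surf, proteins$id), c("id", "description")],
      ann_env$domains
    )
    de <- q_env$de
    de_surf <- tibble(
      protein_id = surf,
      direction = de$direction[match(surf, de$protein_id)]
    )
    de_surf$direction[is.na(de_surf$direction)] <- "none"
    xtab <- crosstab_surfaceome(ann_surf, cats, sets, de_surf)
    readr::write_tsv(xtab, paths[["table2"]], progress = FALSE)
    assign("tally", tally, c_env)
    assign("xtab", xtab, c_env)
    message(sprintf(
      "stage=compare universe=%d surface=%d", length(universe), length(surf)
    ))
  })

  manifest <- list(
    package = "surfaceomics",
    version = as.character(packageVersion("surfaceomics")),
    seed = if (is.null(config)) NA else config$seed,
    parameters = list(
      min_peptides = min_peptides, max_protein_fdr = max_protein_fdr,
      fold_min = fold_min, abs_min = abs_min, bin_size = bin_size,
      evalue_cutoff = evalue_cutoff
    ),
    inputs = as.list(inputs),
    outputs = as.list(paths[names(paths) != "manifest"])
  )
  jsonlite::write_json(manifest, paths[["manifest"]],
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  invisible(list(
    paths = paths,
    annotations = annotations,
    de = q_env$de,
    significance_b = q_env$sigb,
    table1 = c_env$tally,
    table2 = c_env$xtab,
    summary = list(
      n_proteins = nrow(proteins),
      n_surface = sum(annotations$is_surface),
      n_de = sum(q_env$de$direction != "none")
    )
  ))
}

# Evaluate a stage; on error, suffix the stage's existing outputs with
# ".partial" and re-raise naming the stage.
run_stage <- function(name, outputs, code) {
  tryCatch(
    force(code),
    error = function(e) {
      for (p in outputs) {
        if (file.exists(p)) {
          file.rename(p, paste0(p, ".partial"))
        }
      }
      abort(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "surfaceomics_stage_error",
        parent = e
      )
    }
  )
}
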