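#' Configuration for the synthetic surface-proteomics study generator
#'
#' Describes a synthetic study emulating a two-extraction (protoplast
#' formation; cell shaving/shedding), two-condition (pyruvate fermentation;
#' Fe(III)-citrate reduction) surface-proteomics design with duplicate
#' samples, swapped isotope labels in the ratio experiment, cytoplasmic
#' contamination from cell lysis, and compartment-dependent predictor
#' error.
#'
#' Defaults, and why:
#' * `compartment_proportions` — half the proteome cytoplasmic, membrane
#'   proteins dominating the surface classes, a thin cell-wall class:
#'   the composition typical of a Gram-positive proteome.
#' * `lysis_contamination_rate = 0.5` — cell lysis is hard to avoid in both
#'   extraction protocols, so half of all cytoplasmic proteins leak into a
#'   surface extract; this deliberately stresses the classifier.
#' * `contamination_attenuation = 0.3` — contaminants are present but
#'   under-represented relative to their cytoplasmic abundance.
#' * `count_model` — negative-binomial counts (over-dispersion is the norm
#'   in spectral counting) around log-normal per-protein baselines;
#'   `noise = "none"` makes counts exactly equal to their means, for
#'   noise-free oracle checks.
#' * `spike_set = NULL` — 20 differentially expressed proteins, fold 4,
#'   drawn from the surface proteins detected in both conditions, half up
#'   in each condition, with baseline mean at least 20 (a differential
#'   protein far below the absolute-count floor would be undetectable by
#'   design).
#' * `ratio_noise` — log-ratio noise with standard deviation
#'   `scale / sqrt(intensity / reference)`: spread decreasing in intensity,
#'   the assumption behind the intensity-binned outlier statistic.
#'
#' All randomness is drawn from R's Mersenne-Twister generator
#' (inversion for normals), seeded from `seed`, so outputs are
#' byte-identical across platforms for a given configuration.
#'
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param compartment_proportions Named probability vector over the four
#'   truth compartments (`CYTOPLASM`, `CYTOPLASMIC_MEMBRANE`, `CELL_WALL`,
#'   `EXTRACELLULAR`); must sum to 1.
#' @param tool_confusion Named list of per-tool row-stochastic matrices
#'   (4 truth rows x 6 call columns); see [default_tool_confusion()] and
#'   [identity_confusion()].
#' @param lysis_contamination_rate Probability that a cytoplasmic protein
#'   appears in a given surface extract.
#' @param contamination_attenuation Abundance factor applied to
#'   contaminants.
#' @param detection_rate Named vector: probability that a surface protein
#'   is recovered by each extraction experiment.
#' @param cw_domain_prob Probability that a cell-wall protein carries a
#'   LysM or SLH binding domain.
#' @param lipoprotein_rate Probability that an extracellular protein is a
#'   lipoprotein (solute-binding receptors are typically lipid anchored).
#' @param count_model List: `mean_log`, `sd_log` (log-normal baseline
#'   means), `dispersion` (negative-binomial size), `noise` (`"nb"` or
#'   `"none"`).
#' @param spike_set `NULL` for the default described above, or a tibble
#'   with columns `protein` (index into the proteome), `fold` (> 1) and
#'   `up_in` (`"fermentation"` or `"fe_reduction"`).
#' @param n_spikes Number of auto-selected spikes when `spike_set` is
#'   `NULL`.
#' @param ratio_noise List: `scale` (log2 units at the reference
#'   intensity), `mean_log_intensity`, `sd_log_intensity`.
#' @param seed Integer seed.
#' @return A validated `generator_config` object (a list).
#' @export
generator_config <- function(n_proteins = 2000,
                             compartment_proportions = c(
                               CYTOPLASM = 0.50, CYTOPLASMIC_MEMBRANE = 0.35,
                               CELL_WALL = 0.05, EXTRACELLULAR = 0.10
                             ),
                             tool_confusion = default_tool_confusion(),
                             lysis_contamination_rate = 0.5,
                             contamination_attenuation = 0.3,
                             detection_rate = c(protoplast = 0.92, shaving = 0.65),
                             cw_domain_prob = 0.9,
                             lipoprotein_rate = 0.4,
                             count_model = list(
                               mean_log = log(30), sd_log = 0.8,
                               dispersion = 8, noise = "nb"
                             ),
                             spike_set = NULL,
                             n_spikes = 20,
                             ratio_noise = list(
                               scale = 0.3, mean_log_intensity = log(1e6),
                               sd_log_intensity = 1
                             ),
                             seed = 1) {
  stopifnot(n_proteins >= 1)
  if (!setequal(names(compartment_proportions), .truth_compartments)) {
    abort_bad_input("compartment_proportions must be named over the four truth compartments")
  }
  compartment_proportions <- compartment_proportions[.truth_compartments]
  if (any(compartment_proportions < 0) ||
      abs(sum(compartment_proportions) - 1) > 1e-12) {
    abort_bad_input("compartment_proportions must be non-negative and sum to 1 (within 1e-12)")
  }
  if (!setequal(names(tool_confusion), .predictor_tools)) {
    abort_bad_input("tool_confusion must be a named list over the three predictor tools")
  }
  for (tl in .predictor_tools) {
    m <- tool_confusion[[tl]]
    if (!is.matrix(m) || !identical(rownames(m), .truth_compartments) ||
        !identical(colnames(m), .compartments)) {
      abort_bad_input(sprintf(
        "tool_confusion$%s must be a 4x6 matrix with truth rownames and compartment colnames", tl
      ))
    }
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12)) {
      abort_bad_input(sprintf("tool_confusion$%s rows must be probability vectors", tl))
    }
  }
  stopifnot(
    lysis_contamination_rate >= 0, lysis_contamination_rate <= 1,
    contamination_attenuation >= 0, contamination_attenuation <= 1,
    all(detection_rate >= 0), all(detection_rate <= 1),
    cw_domain_prob >= 0, cw_domain_prob <= 1,
    lipoprotein_rate >= 0, lipoprotein_rate <= 1
  )
  if (!setequal(names(detection_rate), c("protoplast", "shaving"))) {
    abort_bad_input("detection_rate must be named over protoplast and shaving")
  }
  count_model$noise <- match.arg(count_model$noise, c("nb", "none"))
  if (!is.null(spike_set)) {
    spike_set <- as_tibble(spike_set)
    stopifnot(all(c("protein", "fold", "up_in") %in% names(spike_set)))
    if (any(spike_set$protein < 1 | spike_set$protein > n_proteins)) {
      abort_bad_input("spike_set references a protein index outside the proteome")
    }
    stopifnot(
      all(spike_set$fold > 1),
      all(spike_set$up_in %in% c("fermentation", "fe_reduction"))
    )
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      compartment_proportions = compartment_proportions,
      tool_confusion = tool_confusion,
      lysis_contamination_rate = lysis_contamination_rate,
      contamination_attenuation = contamination_attenuation,
      detection_rate = detection_rate,
      cw_domain_prob = cw_domain_prob,
      lipoprotein_rate = lipoprotein_rate,
      count_model = count_model,
      spike_set = spike_set,
      n_spikes = as.integer(n_spikes),
      ratio_noise = ratio_noise,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Per-tool confusion matrices
#'
#' `default_tool_confusion()` returns the default noisy truth-to-call
#' matrices: the table-based predictors call the true compartment for most
#' proteins, abstain (`UNKNOWN`) for 8–17%, and misassign a small
#' remainder; the cell-wall and extracellular classes are the hardest.
#' The transmembrane scan only ever reports `CYTOPLASMIC_MEMBRANE` (when it
#' finds helices) or `UNKNOWN`, matching what its one-line output format
#' can express. `identity_confusion()` returns noise-free matrices (every
#' call equals the truth) for all three tools — the limit in which the
#' downstream consensus must recover the ground truth exactly.
#'
#' @return Named list of three row-stochastic matrices.
#' @export
default_tool_confusion <- function() {
  mk <- function(rows) {
    m <- do.call(rbind, rows)
    dimnames(m) <- list(.truth_compartments, .compartments)
    m
  }
  list(
    TMH_SCAN = mk(list(
      c(0, 0.02, 0, 0, 0, 0.98),
      c(0, 0.90, 0, 0, 0, 0.10),
      c(0, 0.01, 0, 0, 0, 0.99),
      c(0, 0.01, 0, 0, 0, 0.99)
    )),
    PSORTB = mk(list(
      c(0.86, 0.02, 0.00, 0.01, 0.03, 0.08),
      c(0.02, 0.84, 0.01, 0.01, 0.04, 0.08),
      c(0.02, 0.03, 0.70, 0.03, 0.07, 0.15),
      c(0.02, 0.02, 0.02, 0.76, 0.08, 0.10)
    )),
    LOCATEP = mk(list(
      c(0.88, 0.02, 0.00, 0.01, 0.00, 0.09),
      c(0.02, 0.85, 0.01, 0.02, 0.00, 0.10),
      c(0.02, 0.04, 0.72, 0.05, 0.00, 0.17),
      c(0.02, 0.03, 0.02, 0.78, 0.00, 0.15)
    ))
  )
}

#' @rdname default_tool_confusion
#' @export
identity_confusion <- function() {
  m <- matrix(0, 4, 6, dimnames = list(.truth_compartments, .compartments))
  m[cbind(.truth_compartments, .truth_compartments)] <- 1
  list(TMH_SCAN = m, PSORTB = m, LOCATEP = m)
}

# tool vocabulary used when materialising calls as files
.raw_vocab <- c(
  CYTOPLASM = "Cytoplasmic",
  CYTOPLASMIC_MEMBRANE = "CytoplasmicMembrane",
  CELL_WALL = "Cellwall",
  EXTRACELLULAR = "Extracellular",
  SURFACE_UNKNOWN = "Non-cytoplasmic",
  UNKNOWN = "Unknown"
)

.category_descriptions <- list(
  TRANSPORT = c(
    "ABC transporter substrate binding protein",
    "TRAP dicarboxylate transporter solute binding subunit",
    "amino acid ABC transporter permease"
  ),
  CHEMOTAXIS = c(
    "methyl-accepting chemotaxis protein",
    "flagellar hook-associated protein"
  ),
  PROTEASE_CW_HYDROLASE = c(
    "cell wall hydrolase",
    "peptidase family M23 protein",
    "signal peptidase I"
  ),
  REDOX = c(
    "4Fe-4S ferredoxin iron-sulfur binding protein",
    "heterodisulfide reductase subunit A",
    "alkyl hydroperoxide reductase"
  ),
  OTHER_UNKNOWN = c(
    "hypothetical protein",
    "protein of unknown function"
  )
)

#' Generate ground-truthed annotation inputs
#'
#' Draws a synthetic proteome with known compartments, per-tool predictor
#' calls from the configured confusion matrices, helix topology consistent
#' with the truth (membrane proteins carry one or more transmembrane
#' helices; the reported topology reflects what the transmembrane scan
#' called), planted cell-wall binding domains on cell-wall proteins, and
#' protein descriptions drawn from a known functional category.
#' Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List with elements `proteins`, `calls`, `topology`, `domains`
#'   and `truth` (per protein: `compartment`, `anchor`, `category`,
#'   `lipoprotein`, `planted_domain`, `is_surface`).
#' @export
generate_annotation_inputs <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_private_seed(config$seed, generate_annotation_inputs_impl(config))
}

generate_annotation_inputs_impl <- function(config) {
  n <- config$n_proteins
  ids <- sprintf("SYN_%05d", seq_len(n))
  truth_comp <- sample(.truth_compartments, n,
    replace = TRUE, prob = config$compartment_proportions
  )
  len <- pmax(60L, as.integer(round(rlnorm(n, log(300), 0.4))))
  len[truth_comp == "CYTOPLASMIC_MEMBRANE"] <-
    pmax(140L, len[truth_comp == "CYTOPLASMIC_MEMBRANE"])

  aa <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  sequence <- vapply(len, function(l) {
    paste(sample(aa, l, replace = TRUE), collapse = "")
  }, character(1))

  # functional category truth; surface classes follow a surfaceome-like mix
  is_surface_truth <- truth_comp != "CYTOPLASM"
  category <- rep("OTHER_UNKNOWN", n)
  category[is_surface_truth] <- sample(
    function_categories(), sum(is_surface_truth), replace = TRUE,
    prob = c(0.33, 0.08, 0.20, 0.05, 0.34)
  )
  category[!is_surface_truth] <- sample(
    c("OTHER_UNKNOWN", "REDOX"), sum(!is_surface_truth),
    replace = TRUE, prob = c(0.9, 0.1)
  )
  description <- vapply(category, function(cat) {
    opts <- .category_descriptions[[cat]]
    opts[[sample.int(length(opts), 1)]]
  }, character(1))

  proteins <- tibble(
    id = ids, description = unname(description),
    sequence = sequence, length = len
  )

  # true topology: membrane proteins carry helices
  truth_topo <- make_truth_topology(truth_comp, len)
  truth_anchor <- vapply(seq_len(n), function(i) {
    interpret_topology(truth_topo$n_helices[[i]], truth_topo$segments[[i]], len[[i]])
  }, character(1))

  # predictor calls from the confusion matrices
  call_list <- lapply(.predictor_tools, function(tl) {
    m <- config$tool_confusion[[tl]]
    call <- vapply(truth_comp, function(tc) {
      sample(.compartments, 1, prob = m[tc, ])
    }, character(1))
    tibble(protein_id = ids, tool = tl, canonical_label = unname(call))
  })
  names(call_list) <- .predictor_tools

  lipoprotein <- truth_comp == "EXTRACELLULAR" &
    runif(n) < config$lipoprotein_rate

  # reported topology follows the TMH call (its file format can only say
  # "helices" or "nothing"); a false-positive call fabricates one helix
  tmh_call <- call_list$TMH_SCAN$canonical_label
  rep_topo <- truth_topo
  for (i in seq_len(n)) {
    says_membrane <- tmh_call[[i]] == "CYTOPLASMIC_MEMBRANE"
    has_helix <- truth_topo$n_helices[[i]] >= 1L
    if (says_membrane && !has_helix) {
      s <- max(2L, as.integer(len[[i]] / 2) - 10L)
      rep_topo$n_helices[[i]] <- 1L
      rep_topo$segments[[i]] <- tibble(start = s, end = s + 20L)
    } else if (!says_membrane && has_helix && tmh_call[[i]] == "UNKNOWN") {
      rep_topo$n_helices[[i]] <- 0L
      rep_topo$segments[[i]] <- tibble(start = integer(), end = integer())
    }
  }
  topology <- tibble(
    protein_id = ids, length = len,
    n_helices = rep_topo$n_helices,
    n_term_side = rep_topo$n_term_side,
    segments = rep_topo$segments
  )

  calls <- bind_rows(lapply(.predictor_tools, function(tl) {
    tb <- call_list[[tl]]
    raw <- if (tl == "TMH_SCAN") {
      sprintf(
        "PredHel=%d Topology=%s",
        topology$n_helices, topology_strings(topology)
      )
    } else {
      unname(.raw_vocab[tb$canonical_label])
    }
    tibble(
      protein_id = tb$protein_id, tool = tl, raw_label = raw,
      canonical_label = tb$canonical_label,
      lipoprotein = if (tl == "LOCATEP") lipoprotein else FALSE,
      secreted = tb$canonical_label == "EXTRACELLULAR",
      lpxtg = FALSE
    )
  }))

  # planted wall-binding domains, plus unrelated background hits
  planted <- rep(NA_character_, n)
  cw <- which(truth_comp == "CELL_WALL")
  take <- cw[runif(length(cw)) < config$cw_domain_prob]
  planted[take] <- sample(c("LYSM", "SLH"), length(take), replace = TRUE)
  wall_acc <- binding_domain_accessions()
  dom_rows <- lapply(which(!is.na(planted)), function(i) {
    acc <- wall_acc[[planted[[i]]]]
    s <- sample.int(max(1L, len[[i]] - 45L), 1)
    tibble(
      protein_id = ids[[i]], accession = acc,
      name = tolower(planted[[i]]),
      ali_start = s, ali_end = s + 40L,
      i_evalue = 10^(-runif(1, 6, 20))
    )
  })
  bg <- which(runif(n) < 0.1)
  dom_rows <- c(dom_rows, lapply(bg, function(i) {
    s <- sample.int(max(1L, len[[i]] - 60L), 1)
    tibble(
      protein_id = ids[[i]], accession = "PF99999", name = "duf_synthetic",
      ali_start = s, ali_end = s + 50L, i_evalue = 10^(-runif(1, 3, 12))
    )
  }))
  domains <- if (length(dom_rows) > 0L) {
    arrange(bind_rows(dom_rows), .data$protein_id)
  } else {
    tibble(
      protein_id = character(), accession = character(), name = character(),
      ali_start = integer(), ali_end = integer(), i_evalue = double()
    )
  }

  truth <- tibble(
    protein_id = ids,
    compartment = truth_comp,
    anchor = truth_anchor,
    category = category,
    lipoprotein = lipoprotein,
    planted_domain = planted,
    is_surface = is_surface_truth
  )
  list(
    proteins = proteins, calls = calls, topology = topology,
    domains = domains, truth = truth
  )
}

make_truth_topology <- function(truth_comp, len) {
  n <- length(truth_comp)
  n_helices <- integer(n)
  n_term_side <- rep("in", n)
  segments <- vector("list", n)
  empty <- tibble(start = integer(), end = integer())
  for (i in seq_len(n)) {
    if (truth_comp[[i]] != "CYTOPLASMIC_MEMBRANE") {
      segments[[i]] <- empty
      next
    }
    l <- len[[i]]
    if (runif(1) < 0.45) {
      n_helices[[i]] <- 1L
      if (runif(1) < 0.5) {
        s <- sample(2:15, 1)
      } else {
        s <- l - 20L - sample(2:15, 1)
      }
      segments[[i]] <- tibble(start = s, end = s + 20L)
    } else {
      k <- min(sample(2:10, 1), (l - 20L) %/% 30L)
      k <- max(2L, k)
      starts <- as.integer(round(seq(5, l - 25, length.out = k)))
      segments[[i]] <- tibble(start = starts, end = starts + 20L)
      n_helices[[i]] <- k
    }
  }
  list(n_helices = n_helices, n_term_side = n_term_side, segments = segments)
}

# "i" / "i98-117o" / "i5-25o40-60i" strings from a topology tibble
topology_strings <- function(topology) {
  vapply(seq_len(nrow(topology)), function(i) {
    side <- if (topology$n_term_side[[i]] == "out") "o" else "i"
    seg <- topology$segments[[i]]
    if (nrow(seg) == 0L) {
      return(side)
    }
    flip <- function(s) if (s == "i") "o" else "i"
    out <- side
    s <- side
    for (j in seq_len(nrow(seg))) {
      out <- paste0(out, seg$start[[j]], "-", seg$end[[j]])
      s <- flip(s)
      out <- paste0(out, s)
    }
    out
  }, character(1))
}

#' Generate ground-truthed quantification inputs
#'
#' Given annotation truth, draws the spectral-count matrix (both extraction
#' experiments, both conditions, duplicate samples; the Fe(III)-reduction
#' duplicates carry 60- and 120-minute treatment metadata), the
#' identification table (detected proteins at two or more peptides, plus
#' decoy records that the identification filter removes), and the
#' dimethyl-label ratio table with a label-swapped duplicate of every row.
#' Cytoplasmic proteins contaminate each extract with the configured lysis
#' rate at attenuated abundance. Spiked proteins carry their fold change in
#' the configured direction in both the counts and the ratios.
#'
#' @param config A [generator_config()].
#' @param truth Truth tibble from [generate_annotation_inputs()].
#' @return List with `counts` (a [spectral_counts()] object),
#'   `identifications`, `ratios` and `truth` (the input truth augmented
#'   with detection, contamination, baseline-mean and spike columns).
#' @export
generate_quantification_inputs <- function(config, truth) {
  stopifnot(inherits(config, "generator_config"))
  with_private_seed(config$seed + 1L, generate_quantification_inputs_impl(config, truth))
}

generate_quantification_inputs_impl <- function(config, truth) {
  n <- nrow(truth)
  ids <- truth$protein_id
  cm <- config$count_model

  detected <- list()
  contaminant <- list()
  for (exp in c("protoplast", "shaving")) {
    p_surface <- config$detection_rate[[exp]]
    det <- logical(n)
    det[truth$is_surface] <- runif(sum(truth$is_surface)) < p_surface
    cont <- logical(n)
    cyto <- !truth$is_surface
    cont[cyto] <- runif(sum(cyto)) < config$lysis_contamination_rate
    det[cyto] <- cont[cyto]
    detected[[exp]] <- det
    contaminant[[exp]] <- cont
  }

  baseline <- rlnorm(n, cm$mean_log, cm$sd_log)

  spike <- config$spike_set
  if (is.null(spike)) {
    candidates <- which(truth$is_surface & detected$protoplast & detected$shaving)
    k <- min(config$n_spikes, length(candidates))
    pick <- sort(candidates[sample.int(length(candidates), k)])
    spike <- tibble(
      protein = pick,
      fold = rep(4, k),
      up_in = rep(c("fermentation", "fe_reduction"), length.out = k)
    )
  }
  baseline[spike$protein] <- pmax(baseline[spike$protein], 20)

  fold_ferm <- rep(1, n)
  fold_fe <- rep(1, n)
  fold_ferm[spike$protein[spike$up_in == "fermentation"]] <-
    spike$fold[spike$up_in == "fermentation"]
  fold_fe[spike$protein[spike$up_in == "fe_reduction"]] <-
    spike$fold[spike$up_in == "fe_reduction"]

  samples <- tibble(
    sample_id = c(
      "protoplast.ferm.R1", "protoplast.ferm.R2",
      "protoplast.fe.R1", "protoplast.fe.R2",
      "shaving.ferm.R1", "shaving.ferm.R2",
      "shaving.fe.R1", "shaving.fe.R2"
    ),
    experiment = rep(c("protoplast", "shaving"), each = 4),
    condition = rep(rep(c("fermentation", "fe_reduction"), each = 2), 2),
    replicate = rep(c("R1", "R2"), 4),
    treatment_minutes = rep(c(NA, NA, 60, 120), 2)
  )
  draw <- function(mu) {
    if (cm$noise == "none") {
      round(mu)
    } else {
      rnbinom(length(mu), mu = mu, size = cm$dispersion)
    }
  }
  counts <- matrix(0, n, nrow(samples), dimnames = list(ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    exp <- samples$experiment[[j]]
    cond_fold <- if (samples$condition[[j]] == "fermentation") fold_ferm else fold_fe
    mu <- baseline * cond_fold
    mu[contaminant[[exp]]] <- mu[contaminant[[exp]]] * config$contamination_attenuation
    mu[!detected[[exp]]] <- 0
    drawn <- draw(mu)
    drawn[!detected[[exp]]] <- 0
    counts[, j] <- drawn
  }
  scm <- spectral_counts(counts, samples)

  # identification table: detected proteins pass the two-peptide/FDR filter,
  # decoys are planted below it
  ident <- bind_rows(lapply(c("protoplast", "shaving"), function(exp) {
    det_ids <- ids[detected[[exp]]]
    real <- tidyr::expand_grid(
      protein_id = det_ids,
      condition = c("fermentation", "fe_reduction"),
      replicate = c("R1", "R2")
    ) |>
      mutate(
        experiment = exp,
        n_peptides = 2L + rpois(dplyr::n(), 3),
        protein_fdr = runif(dplyr::n(), 0, 0.01)
      )
    n_decoy <- max(1L, as.integer(round(0.1 * length(det_ids))))
    decoy <- tibble(
      protein_id = sprintf("DECOY_%s_%04d", toupper(substr(exp, 1, 2)), seq_len(n_decoy)),
      condition = "fermentation",
      replicate = "R1",
      experiment = exp,
      n_peptides = 1L,
      protein_fdr = runif(n_decoy, 0.02, 0.5)
    )
    bind_rows(real, decoy)
  })) |>
    select("protein_id", "experiment", "condition", "replicate", "n_peptides", "protein_fdr")

  # ratio table for the shaving comparison, duplicated with swapped labels
  sh_ids <- which(detected$shaving)
  rn <- config$ratio_noise
  intensity <- rlnorm(length(sh_ids), rn$mean_log_intensity, rn$sd_log_intensity)
  true_log2 <- log2(fold_fe[sh_ids]) - log2(fold_ferm[sh_ids])
  sd_i <- rn$scale / sqrt(intensity / exp(rn$mean_log_intensity))
  fwd <- true_log2 + rnorm(length(sh_ids), 0, sd_i)
  rev <- -(true_log2 + rnorm(length(sh_ids), 0, sd_i))
  ratios <- bind_rows(
    tibble(
      protein_id = ids[sh_ids], log2_ratio = fwd, intensity = intensity,
      comparison = "fe_reduction_vs_fermentation", label_swapped = FALSE
    ),
    tibble(
      protein_id = ids[sh_ids], log2_ratio = rev, intensity = intensity,
      comparison = "fe_reduction_vs_fermentation", label_swapped = TRUE
    )
  )

  de_status <- rep("none", n)
  de_status[spike$protein] <- spike$up_in
  true_fold <- rep(1, n)
  true_fold[spike$protein] <- spike$fold

  truth_aug <- truth |>
    mutate(
      baseline_mean = baseline,
      detected_protoplast = detected$protoplast,
      detected_shaving = detected$shaving,
      contaminant_protoplast = contaminant$protoplast,
      contaminant_shaving = contaminant$shaving,
      de_status = de_status,
      true_fold = true_fold
    )
  list(counts = scm, identifications = ident, ratios = ratios, truth = truth_aug)
}

#' Simulate a complete synthetic study
#'
#' Runs [generate_annotation_inputs()] and
#' [generate_quantification_inputs()] under the configured seed and
#' returns all inputs plus the merged ground truth.
#'
#' @param config A [generator_config()].
#' @return List with `proteins`, `calls`, `topology`, `domains`, `counts`,
#'   `identifications`, `ratios`, `truth` and `config`.
#' @export
simulate_study <- function(config = generator_config()) {
  ann <- generate_annotation_inputs(config)
  quant <- generate_quantification_inputs(config, ann$truth)
  list(
    proteins = ann$proteins, calls = ann$calls, topology = ann$topology,
    domains = ann$domains, counts = quant$counts,
    identifications = quant$identifications, ratios = quant$ratios,
    truth = quant$truth, config = config
  )
}

#' Write a simulated study to disk in the formats the package reads
#'
#' Materialises a [simulate_study()] result as the input files of a real
#' study: FASTA proteome, one-line transmembrane-scan output, PSORTb-style
#' and LocateP-style tables, an hmmscan per-domain table, identification
#' and spectral-count TSVs, the ratio table, and `truth.tsv`.
#'
#' @param sim List from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    proteome = file.path(dir, "proteome.fasta"),
    tmh_scan = file.path(dir, "tmh_scan.txt"),
    psortb = file.path(dir, "psortb.tsv"),
    locatep = file.path(dir, "locatep.tsv"),
    domains = file.path(dir, "domains.domtbl"),
    identifications = file.path(dir, "identifications.tsv"),
    counts = file.path(dir, "spectral_counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    ratios = file.path(dir, "ratios.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(sim$proteins, paths[["proteome"]])

  topo_str <- topology_strings(sim$topology)
  tmh_lines <- sprintf(
    "%s\tlen=%d\tExpAA=%.2f\tFirst60=%.2f\tPredHel=%d\tTopology=%s",
    sim$topology$protein_id, sim$topology$length,
    21 * sim$topology$n_helices, 0, sim$topology$n_helices, topo_str
  )
  writeLines(tmh_lines, paths[["tmh_scan"]])

  psortb <- sim$calls |> filter(.data$tool == "PSORTB")
  readr::write_tsv(
    tibble(SeqID = psortb$protein_id, Localization = psortb$raw_label, Score = 9.97),
    paths[["psortb"]],
    progress = FALSE
  )
  locatep <- sim$calls |> filter(.data$tool == "LOCATEP")
  readr::write_tsv(
    tibble(
      protein_id = locatep$protein_id,
      localization = locatep$raw_label,
      lipoprotein = ifelse(locatep$lipoprotein, "yes", "no")
    ),
    paths[["locatep"]],
    progress = FALSE
  )

  d <- sim$domains
  if (nrow(d) > 0L) {
    dom_lines <- sprintf(
      paste(
        "%s %s 120 %s - 400 %.1e 50.0 0.1 1 1 %.1e %.1e 48.0 0.1",
        "1 40 %d %d %d %d 0.95 synthetic domain"
      ),
      d$name, d$accession, d$protein_id, d$i_evalue, d$i_evalue, d$i_evalue,
      d$ali_start, d$ali_end, d$ali_start, d$ali_end
    )
  } else {
    dom_lines <- character(0)
  }
  writeLines(
    c("# synthetic hmmscan per-domain table", dom_lines, "#"),
    paths[["domains"]]
  )

  write_identifications(sim$identifications, paths[["identifications"]])
  write_spectral_counts(sim$counts, paths[["counts"]], paths[["samples"]])
  write_ratio_table(sim$ratios, paths[["ratios"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
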