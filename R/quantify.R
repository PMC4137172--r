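#' Normalize spectral counts to a common per-sample total
#'
#' Implements "normalized total spectra" scaling: the sum of spectral counts
#' over all proteins in each sample is adjusted to a common value — the mean
#' of the raw per-sample totals — by multiplying every count in sample *j*
#' by `common_value / total_j`. Rank order of proteins within a sample is
#' conserved; after scaling, every per-sample total equals the common value
#' to within relative tolerance 1e-9.
#'
#' @param x A [spectral_counts()] object, or a bare numeric matrix with
#'   proteins in rows and samples in columns.
#' @return A list with elements `normalized` (same type as the input, real
#'   valued), `scale_factors` (named per-sample vector) and `common_value`.
#'   A sample with total 0 is an error naming the sample.
#' @export
#' @examples
#' m <- matrix(c(60, 40, 100, 200), 2, 2,
#'   dimnames = list(c("p1", "p2"), c("s1", "s2"))
#' )
#' normalize_total_spectra(m)$scale_factors
normalize_total_spectra <- function(x) {
  m <- if (inherits(x, "spectral_counts")) x$counts else x
  if (!is.matrix(m) || ncol(m) < 1L) {
    abort_bad_input("need a proteins-by-samples matrix with at least one sample")
  }
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero)) {
    abort_bad_input(sprintf(
      "sample(s) with zero total spectral count: %s",
      paste(colnames(m)[zero] %||% which(zero), collapse = ", ")
    ))
  }
  common <- mean(totals)
  factors <- common / totals
  norm <- sweep(m, 2L, factors, `*`)
  out <- if (inherits(x, "spectral_counts")) {
    structure(list(counts = norm, samples = x$samples), class = "spectral_counts")
  } else {
    norm
  }
  list(normalized = out, scale_factors = factors, common_value = common)
}

#' Summarise replicate counts for one protein in one condition
#'
#' The mean is the arithmetic mean of the replicate values. The error is
#' either the sample standard deviation (`error_mode = "sd"`, the estimator
#' used for conditions with pooled replicates) or the semi-difference
#' `|x1 - x2| / 2` (`error_mode = "semi_difference"`, for strict duplicates;
#' requires exactly two values). A single value has error 0.
#'
#' @param values Numeric replicate values (length >= 1).
#' @param error_mode `"sd"` or `"semi_difference"`.
#' @return A list with `mean`, `error`, `error_mode`, `n`.
#' @export
#' @examples
#' summarize_condition(c(10, 14), "semi_difference")
summarize_condition <- function(values, error_mode = c("sd", "semi_difference")) {
  error_mode <- match.arg(error_mode)
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values))) {
    abort_bad_input("values must be one or more finite numbers")
  }
  n <- length(values)
  err <- if (n == 1L) {
    0
  } else if (error_mode == "sd") {
    sd(values)
  } else {
    if (n != 2L) {
      abort_bad_input("semi_difference error mode requires exactly two replicates")
    }
    abs(values[[1]] - values[[2]]) / 2
  }
  list(mean = mean(values), error = err, error_mode = error_mode, n = n)
}

#' Call differential expression between two conditions
#'
#' Semi-quantitative spectral-count rule: a protein is called more expressed
#' in one condition when its mean count there is (i) at least `fold_min`
#' times the mean in the other condition, (ii) higher by an absolute value
#' of at least `abs_min` (guarding against unreliable very low counts), and
#' (iii) separated after accounting for the error — the intervals
#' mean ± error of the two conditions must not overlap
#' (`hi - err_hi > lo + err_lo`, strictly). A zero mean in the lower
#' condition satisfies the fold criterion whenever the higher mean does not
#' vanish; the fold is then reported as `Inf`. Swapping the two conditions
#' flips the direction and changes nothing else.
#'
#' @param summary_a,summary_b Per-condition summaries: either single
#'   summaries from [summarize_condition()], or tibbles with columns
#'   `protein_id`, `mean`, `error` (matched by `protein_id`).
#' @param fold_min Minimum fold change (default 2).
#' @param abs_min Minimum absolute difference in normalized counts
#'   (default 5).
#' @return A tibble with columns `protein_id` (if supplied), `direction`
#'   (`up_in_A`, `up_in_B` or `none`), `fold`, `abs_diff`, `separated`.
#' @export
#' @examples
#' call_differential_expression(
#'   list(mean = 13, error = 1), list(mean = 4, error = 1)
#' )
call_differential_expression <- function(summary_a, summary_b,
                                         fold_min = 2, abs_min = 5) {
  a <- de_side(summary_a)
  b <- de_side(summary_b)
  if (!is.null(a$protein_id) && !is.null(b$protein_id)) {
    if (!setequal(a$protein_id, b$protein_id)) {
      abort_bad_input("the two summaries cover different proteins")
    }
    o <- match(a$protein_id, b$protein_id)
    b <- lapply(b, function(v) v[o])
  }
  hi <- pmax(a$mean, b$mean)
  lo <- pmin(a$mean, b$mean)
  err_hi <- ifelse(a$mean >= b$mean, a$error, b$error)
  err_lo <- ifelse(a$mean >= b$mean, b$error, a$error)
  fold <- ifelse(hi == lo, 1, ifelse(lo == 0, Inf, hi / lo))
  abs_diff <- hi - lo
  separated <- (hi - err_hi) > (lo + err_lo)
  called <- (fold >= fold_min) & (abs_diff >= abs_min) & separated
  direction <- ifelse(!called, "none", ifelse(a$mean > b$mean, "up_in_A", "up_in_B"))
  out <- tibble(
    direction = direction, fold = fold, abs_diff = abs_diff, separated = separated
  )
  if (!is.null(a$protein_id)) {
    out <- bind_cols(tibble(protein_id = a$protein_id), out)
  }
  out
}

de_side <- function(s) {
  if (is.data.frame(s)) {
    stopifnot(all(c("mean", "error") %in% names(s)))
    list(
      protein_id = if ("protein_id" %in% names(s)) s$protein_id else NULL,
      mean = as.numeric(s$mean), error = as.numeric(s$error)
    )
  } else {
    list(protein_id = NULL, mean = as.numeric(s$mean), error = as.numeric(s$error))
  }
}

#' Spectral-count differential expression between two conditions
#'
#' Convenience wrapper running the full spectral-count comparison on a
#' [spectral_counts()] object: normalize to the common total, average the
#' replicates of each condition with the chosen error estimator, and apply
#' [call_differential_expression()] to every protein.
#'
#' @param x A [spectral_counts()] object (typically one experiment's
#'   samples).
#' @param condition_a,condition_b Condition labels in `x$samples$condition`.
#' @param error_mode_a,error_mode_b Error estimator per condition
#'   (`"semi_difference"` for strict duplicates, `"sd"` otherwise).
#' @param fold_min,abs_min Thresholds of the rule.
#' @return Tibble with per-protein means, errors and the differential call;
#'   direction `up_in_A` refers to `condition_a`.
#' @export
spectral_de <- function(x, condition_a = "fermentation",
                        condition_b = "fe_reduction",
                        error_mode_a = "semi_difference",
                        error_mode_b = "sd",
                        fold_min = 2, abs_min = 5) {
  stopifnot(inherits(x, "spectral_counts"))
  norm <- normalize_total_spectra(x)$normalized
  side <- function(cond, mode) {
    cols <- which(norm$samples$condition == cond)
    if (length(cols) == 0L) {
      abort_bad_input(sprintf("no samples with condition '%s'", cond))
    }
    vals <- norm$counts[, cols, drop = FALSE]
    s <- apply(vals, 1L, function(v) {
      z <- summarize_condition(v, mode)
      c(z$mean, z$error)
    })
    tibble(
      protein_id = rownames(norm$counts),
      mean = s[1, ], error = s[2, ], n = length(cols)
    )
  }
  sa <- side(condition_a, error_mode_a)
  sb <- side(condition_b, error_mode_b)
  calls <- call_differential_expression(sa, sb, fold_min = fold_min, abs_min = abs_min)
  sa |>
    rename(mean_a = "mean", error_a = "error", n_a = "n") |>
    left_join(
      rename(sb, mean_b = "mean", error_b = "error", n_b = "n"),
      by = "protein_id"
    ) |>
    left_join(calls, by = "protein_id")
}

#' Relative expression by the comparative Ct method
#'
#' Computes the qPCR delta-Ct of a target gene relative to a reference gene
#' in each of two conditions, their difference delta-delta-Ct (condition A
#' relative to condition B), and the derived relative expression levels:
#' `2^-delta_ct` within each condition and the cross-condition fold change
#' `2^-delta_delta_ct`.
#'
#' @param ct_target_a,ct_ref_a Target and reference Ct in condition A.
#' @param ct_target_b,ct_ref_b Target and reference Ct in condition B.
#' @param gene Optional gene label(s).
#' @return Tibble with one row per gene: the four Ct inputs, `delta_ct_a`,
#'   `delta_ct_b`, `rel_expression_a`, `rel_expression_b`,
#'   `delta_delta_ct`, `fold`.
#' @export
#' @examples
#' delta_delta_ct(25, 15, 18, 15) # fold 2^-7
delta_delta_ct <- function(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b,
                           gene = "gene") {
  stopifnot(
    all(ct_target_a > 0), all(ct_ref_a > 0),
    all(ct_target_b > 0), all(ct_ref_b > 0)
  )
  dct_a <- ct_target_a - ct_ref_a
  dct_b <- ct_target_b - ct_ref_b
  ddct <- dct_a - dct_b
  tibble(
    gene = gene,
    ct_target_a = ct_target_a, ct_ref_a = ct_ref_a,
    ct_target_b = ct_target_b, ct_ref_b = ct_ref_b,
    delta_ct_a = dct_a, delta_ct_b = dct_b,
    rel_expression_a = 2^(-dct_a), rel_expression_b = 2^(-dct_b),
    delta_delta_ct = ddct, fold = 2^(-ddct)
  )
}
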