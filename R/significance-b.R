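#' Significance B: intensity-binned robust outlier statistic for log-ratios
#'
#' Scores each protein's log2 ratio against the spread of ratios of proteins
#' of similar intensity, on the premise that ratio noise depends on
#' intensity. Rows are sorted by intensity and cut into consecutive bins of
#' at least `bin_size` rows (the remainder joins the last bin; fewer than
#' `bin_size` rows in total form a single bin). Within each bin, with
#' m the median, u the 84.13th and l the 15.87th percentile of the log2
#' ratios (linear interpolation), the robust z-score of ratio r is
#' `(r - m) / (u - m)` for r at or above the median and `-(m - r) / (m - l)`
#' below it — the percentile distances play the role of one standard
#' deviation on each side. The two-sided tail probability is
#' `p = erfc(|z| / sqrt(2))`, capped at 1, so a ratio at the bin median has
#' p = 1. A degenerate side (u = m or m = l) gets z = 0. p-values are
#' adjusted across all proteins by Benjamini-Hochberg.
#'
#' The result is invariant to the input row order: ties in intensity are
#' broken deterministically (by protein id, then ratio) before binning.
#'
#' @param ratios Ratio tibble with columns `protein_id`, `log2_ratio`,
#'   `intensity` (positive; non-positive intensities are an error).
#' @param bin_size Minimum rows per intensity bin (default 300, >= 3).
#' @param center If `TRUE`, median-center the log2 ratios within each bin
#'   before scoring (off by default; no re-centering is applied).
#' @return The input rows (original order) with columns `bin_index`,
#'   `robust_z` (signed), `p` and `p_adjusted` appended.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   protein_id = sprintf("p%02d", 1:20),
#'   log2_ratio = c(rnorm(19), 5), intensity = exp(rnorm(20, 10))
#' )
#' significance_b(tab, bin_size = 20)
significance_b <- function(ratios, bin_size = 300, center = FALSE) {
  validate_ratio_table(ratios)
  if (nrow(ratios) < 1L) {
    abort_bad_input("ratio table must have at least one row")
  }
  if (bin_size < 3) {
    abort_bad_input("bin_size must be at least 3")
  }
  n <- nrow(ratios)
  ord <- order(ratios$intensity, ratios$protein_id, ratios$log2_ratio)
  n_bins <- max(1L, n %/% as.integer(bin_size))
  bin_sorted <- pmin(((seq_len(n) - 1L) %/% as.integer(bin_size)) + 1L, n_bins)

  r_sorted <- ratios$log2_ratio[ord]
  z_sorted <- numeric(n)
  for (b in seq_len(n_bins)) {
    idx <- which(bin_sorted == b)
    r <- r_sorted[idx]
    if (center) {
      r <- r - median(r)
    }
    m <- median(r)
    u <- quantile(r, 0.8413, names = FALSE, type = 7)
    l <- quantile(r, 0.1587, names = FALSE, type = 7)
    up <- r >= m
    z <- numeric(length(r))
    z[up] <- if (u > m) (r[up] - m) / (u - m) else 0
    z[!up] <- if (m > l) -(m - r[!up]) / (m - l) else 0
    z_sorted[idx] <- z
  }
  z <- numeric(n)
  bin_index <- integer(n)
  z[ord] <- z_sorted
  bin_index[ord] <- bin_sorted
  p <- pmin(1, 2 * pnorm(-abs(z))) # erfc(|z|/sqrt(2))
  out <- as_tibble(ratios)
  out$bin_index <- bin_index
  out$robust_z <- z
  out$p <- p
  out$p_adjusted <- p.adjust(p, method = "BH")
  out
}
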