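# Expression-divergence metrics and the contingency statistics used in the
# comparative analyses.

#' Symmetric log2 fold change between two TPM values
#'
#' log2((max + eps) / (min + eps)); always nonnegative and symmetric in its
#' arguments. The pseudocount keeps zero-TPM genes finite (default 1).
#'
#' @param tpm_a,tpm_b Nonnegative TPM vectors (recycled).
#' @param eps Pseudocount.
#' @return Nonnegative numeric vector.
#' @export
log2_fold_change <- function(tpm_a, tpm_b, eps = 1) {
  if (any(tpm_a < 0, na.rm = TRUE) || any(tpm_b < 0, na.rm = TRUE)) stopf("negative TPM")
  hi <- pmax(tpm_a, tpm_b); lo <- pmin(tpm_a, tpm_b)
  log2((hi + eps) / (lo + eps))
}

TPM_DIFF_BINS <- c("0-1", "1-5", "5-10", ">10")

#' Bin absolute TPM differences
#'
#' Half-open bins [0,1), [1,5), [5,10), [10, Inf) over |TPM_a - TPM_b|.
#'
#' @param tpm_a,tpm_b TPM vectors.
#' @return Named integer vector of counts per bin (sums to input length).
#' @export
tpm_diff_bins <- function(tpm_a, tpm_b) {
  d <- abs(tpm_a - tpm_b)
  cut_idx <- findInterval(d, c(0, 1, 5, 10))
  counts <- tabulate(cut_idx, nbins = 4L)
  setNames(counts, TPM_DIFF_BINS)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Yates continuity correction on by default (the convention that reproduces
#' the published statistic on its printed input counts). P-values below the
#' double-precision floor are reported as "<2.2e-16" in `p_label`.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @param correction Apply Yates correction (default TRUE).
#' @return List with table, chi2, p_value, p_label, correction.
#' @export
chi_square_2x2 <- function(table, correction = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stopf("table must be 2x2")
  if (any(table < 0)) stopf("negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) stopf("zero margin")
  ht <- suppressWarnings(chisq.test(table, correct = correction))
  p <- ht$p.value
  list(table = table, chi2 = unname(ht$statistic), p_value = p,
       p_label = if (p < 2.2e-16) "<2.2e-16" else format(p, digits = 4),
       correction = correction)
}

#' Flag differentially expressed genes
#'
#' flag <=> p < 0.05 and |log2FC| > 1, both strict.
#'
#' @param log2fc Per-gene log2 fold changes.
#' @param p_values Per-gene p-values (same length).
#' @param p_cut,fc_cut Thresholds.
#' @return Logical vector.
#' @export
deg_filter <- function(log2fc, p_values, p_cut = 0.05, fc_cut = 1) {
  if (length(log2fc) != length(p_values)) stopf("length mismatch")
  p_values < p_cut & abs(log2fc) > fc_cut
}

#' Signed percentage shift in marked-gene counts
#'
#' (tetraploid count - diploid count) / tetrad total * 100, the convention
#' consistent with the published shift percentages.
#'
#' @param count_diploid,count_tetraploid Marked-gene counts.
#' @param denominator Total number of tetrads.
#' @return Signed percentage.
#' @export
marked_gene_shift <- function(count_diploid, count_tetraploid, denominator) {
  if (any(denominator == 0)) stopf("zero denominator")
  if (any(count_diploid > denominator) || any(count_tetraploid > denominator)) {
    stopf("count exceeds denominator")
  }
  (count_tetraploid - count_diploid) / denominator * 100
}

#' Pearson correlation between promoter signal and expression
#'
#' Correlates per-gene promoter peak scores with log2(TPM + 1).
#'
#' @param signal Per-gene signal vector.
#' @param tpm Per-gene TPM vector (same length).
#' @return Pearson r.
#' @export
signal_expression_correlation <- function(signal, tpm) {
  if (length(signal) != length(tpm)) stopf("length mismatch")
  if (length(signal) < 3) stopf("need n >= 3")
  y <- log2(tpm + 1)
  if (stats::sd(signal) == 0 || stats::sd(y) == 0) stopf("zero variance")
  cor(signal, y)
}

#' Proportion as a percentage
#' @param count,total Counts.
#' @return `count / total * 100`.
#' @export
proportion_pct <- function(count, total) {
  if (any(total == 0)) stopf("zero total")
  count / total * 100
}
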