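# Gene filtering and between-sample normalization preparing raw counts for
# differential expression and MI estimation.

#' Filter genes by mean raw expression
#'
#' Keeps exactly the genes whose mean across all samples is strictly greater
#' than `threshold` (so a gene with mean exactly equal to the threshold is
#' dropped). Applied to raw counts, before normalization. Idempotent.
#'
#' @param matrix genes-by-samples matrix.
#' @param threshold strict lower bound on the across-sample mean (default 10).
#' @return the filtered matrix, sample set and gene order unchanged.
#' @export
filter_by_mean <- function(matrix, threshold = 10) {
  validate_expression(matrix, nonnegative = TRUE)
  keep <- rowMeans(matrix) > threshold
  if (!any(keep)) warnf("filter_by_mean: no gene exceeds mean %g", threshold)
  matrix[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values (TMM) scale factors
#'
#' Composition-bias normalization for count libraries: each sample's factor
#' is 2 to the weighted trimmed mean of per-gene log2 ratios (M) against a
#' reference sample, trimming 30% on M and 5% on A, with precision
#' (inverse approximate variance) weights; genes with a zero count in either
#' sample are excluded. The reference is the sample whose upper quartile is
#' closest to the mean upper quartile. Factors are rescaled so their
#' geometric mean is 1 (the convention of count-based DE tools). Computation
#' is delegated to \pkg{edgeR}'s TMM implementation.
#'
#' @param matrix raw count matrix (genes x samples), at least two samples.
#' @param reference optional sample identifier to use as the reference
#'   column; by default chosen by the upper-quartile rule.
#' @return named numeric vector of positive factors, one per sample.
#' @export
tmm_factors <- function(matrix, reference = NULL) {
  validate_expression(matrix, nonnegative = TRUE)
  if (ncol(matrix) < 2L) stopf("tmm_factors: at least two samples required")
  zero <- colSums(matrix) == 0
  if (any(zero))
    stopf("tmm_factors: sample '%s' has all-zero counts", colnames(matrix)[zero][1])
  ref_col <- NULL
  if (!is.null(reference)) {
    ref_col <- match(reference, colnames(matrix))
    if (is.na(ref_col)) stopf("tmm_factors: unknown reference sample '%s'", reference)
  }
  f <- edgeR::calcNormFactors(matrix, method = "TMM", refColumn = ref_col,
                              logratioTrim = 0.30, sumTrim = 0.05,
                              doWeighting = TRUE)
  stats::setNames(as.numeric(f), colnames(matrix))
}

#' Log2 counts-per-million on TMM-effective library sizes
#'
#' `log2((count + prior_count) / (library_size * factor) * 1e6)`: finite at
#' zero counts and strictly monotone in the count within a sample.
#'
#' @param matrix raw count matrix.
#' @param factors named positive factors from [tmm_factors()].
#' @param prior_count pseudo-count added before the log (default 1).
#' @return matrix of log2-CPM values with the same dimnames.
#' @export
log_cpm <- function(matrix, factors, prior_count = 1) {
  validate_expression(matrix, nonnegative = TRUE)
  if (is.null(names(factors))) names(factors) <- colnames(matrix)
  factors <- factors[colnames(matrix)]
  if (anyNA(factors) || any(!is.finite(factors)) || any(factors <= 0))
    stopf("log_cpm: factors must be finite and positive for every sample")
  eff_lib <- colSums(matrix) * factors
  log2(sweep(matrix + prior_count, 2, eff_lib, "/") * 1e6)
}

#' One-call normalization: mean filter, TMM, log2-CPM
#'
#' @param counts raw count matrix.
#' @param min_mean strict mean filter threshold (default 10).
#' @param prior_count pseudo-count for [log_cpm()].
#' @return list with `normalized` (log2-CPM matrix of the retained genes)
#'   and `scale_factors` (named TMM factors).
#' @export
normalize_counts <- function(counts, min_mean = 10, prior_count = 1) {
  filtered <- filter_by_mean(counts, min_mean)
  factors <- tmm_factors(filtered)
  list(normalized = log_cpm(filtered, factors, prior_count),
       scale_factors = factors)
}
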