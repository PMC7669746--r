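# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    (if (positive) x >= 1 else x >= 0)
}

#' @noRd
# C-locale (radix) ordering so edge ranking never depends on the session locale.
radix_order <- function(...) order(..., method = "radix")

edge_key <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "\t")

key_to_pair <- function(key) {
  parts <- strsplit(key, "\t", fixed = TRUE)
  data.frame(
    gene_a = vapply(parts, `[[`, character(1), 1L),
    gene_b = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

# Chromosome labels tolerate UCSC ("chr1") and GENCODE ("1") dialects.
normalize_chrom <- function(x) toupper(sub("^chr", "", as.character(x), ignore.case = TRUE))

#' Validate a genes-by-samples expression matrix
#'
#' The package's expression container is a plain numeric matrix with unique
#' gene identifiers as rownames and unique sample identifiers as colnames,
#' holding non-negative values and no missing entries.
#'
#' @param x object to validate.
#' @param what label used in error messages.
#' @param nonnegative require non-negative values (TRUE for raw counts;
#'   log-scale matrices are legitimately negative).
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression <- function(x, what = "expression matrix",
                                nonnegative = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stopf("%s must have unique gene identifiers as rownames", what)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stopf("%s must have unique sample identifiers as colnames", what)
  if (anyNA(x)) stopf("%s contains missing values", what)
  if (nonnegative && any(x < 0)) stopf("%s contains negative values", what)
  invisible(x)
}
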