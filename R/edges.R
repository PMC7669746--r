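# MI-ranked edge lists: the object every network cut-off acts on.
#
# Canonical form: gene_a < gene_b (C-locale), rows sorted by MI descending
# with ties broken lexicographically by (gene_a, gene_b). Deterministic
# ordering makes top-N cut-offs reproducible without a seed.

#' Canonical MI-ranked edge list
#'
#' Builds the canonical ranked edge list used throughout the package:
#' undirected gene pairs weighted by mutual information, stored with
#' `gene_a < gene_b` and sorted by decreasing MI (ties broken by the pair's
#' lexicographic order). Self-loops, duplicate pairs, negative or missing
#' MI values are rejected.
#'
#' @param gene_a,gene_b character vectors of gene identifiers.
#' @param mi non-negative numeric vector of mutual-information weights.
#' @return a `data.frame` of class `mi_edges` with columns
#'   `gene_a`, `gene_b`, `mi` in canonical order.
#' @examples
#' mi_edges(c("B", "C"), c("A", "A"), c(0.5, 0.9))
#' @export
mi_edges <- function(gene_a, gene_b, mi) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  mi <- as.numeric(mi)
  if (length(gene_a) != length(gene_b) || length(gene_a) != length(mi))
    stopf("gene_a, gene_b and mi must have equal length")
  if (anyNA(gene_a) || anyNA(gene_b) || anyNA(mi))
    stopf("edge list contains missing values")
  if (any(mi < 0))
    stopf("negative mutual information at row %d", which(mi < 0)[1])
  if (any(gene_a == gene_b))
    stopf("self-loop on gene '%s' (row %d)",
          gene_a[gene_a == gene_b][1], which(gene_a == gene_b)[1])
  swap <- radix_order_pairwise(gene_a, gene_b)
  a <- ifelse(swap, gene_b, gene_a)
  b <- ifelse(swap, gene_a, gene_b)
  key <- edge_key(a, b)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stopf("duplicate edge for pair (%s)", gsub("\t", ", ", dup, fixed = TRUE))
  }
  o <- radix_order(-mi, a, b)
  out <- data.frame(gene_a = a[o], gene_b = b[o], mi = mi[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("mi_edges", "data.frame")
  out
}

# TRUE where the pair must be swapped to satisfy gene_a < gene_b in C locale.
# Vectorized via a radix rank of the pooled strings (stable, locale-free):
# for each row the two strings differ, so rank order equals string order.
radix_order_pairwise <- function(a, b) {
  n <- length(a)
  if (n == 0L) return(logical(0))
  x <- c(a, b)
  r <- integer(2L * n)
  r[radix_order(x)] <- seq_len(2L * n)
  r[seq_len(n)] > r[n + seq_len(n)]
}

#' @export
print.mi_edges <- function(x, ...) {
  cat(sprintf("MI-ranked edge list: %d edges, %d genes\n",
              nrow(x), length(unique(c(x$gene_a, x$gene_b)))))
  if (nrow(x) > 0)
    print.data.frame(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}

as_mi_edges <- function(df) {
  mi <- if ("mi" %in% names(df)) df$mi else rep(0, nrow(df))
  mi_edges(df$gene_a, df$gene_b, mi)
}

#' Keep the top-N highest-MI edges
#'
#' Returns the first `min(n, nrow(edges))` rows of a canonical ranked edge
#' list. Because ranking is deterministic (MI descending, lexicographic
#' tie-break), cut-offs are nested: `top_n(e, 100)` is a prefix of
#' `top_n(e, 1000)`.
#'
#' @param edges an `mi_edges` edge list.
#' @param n positive integer cut-off.
#' @return an `mi_edges` edge list with at most `n` rows.
#' @export
top_n <- function(edges, n) {
  stopifnot(inherits(edges, "mi_edges"))
  if (!is_count(n)) stopf("n must be a positive integer")
  out <- edges[seq_len(min(n, nrow(edges))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mi_edges", "data.frame")
  out
}

edge_keys <- function(edges) {
  if (inherits(edges, "mi_edges") || is.data.frame(edges))
    edge_key(edges$gene_a, edges$gene_b)
  else as.character(edges)
}
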