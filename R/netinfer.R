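# Mutual-information co-expression inference.
#
# The estimator is the discrete plug-in MI on an equal-frequency binning of
# each expression profile (B = floor(sqrt(n)) bins by default), with an
# optional Miller-Madow bias correction. Binning breaks within-vector ties
# by original index, so the partition — and therefore every MI value and
# every top-N cut-off — is deterministic without a seed, and MI is exactly
# invariant under strictly increasing transforms of either profile.

#' MI estimator configuration
#'
#' @param n_bins `"sqrt_n"` (default: `floor(sqrt(n))` bins) or an explicit
#'   integer >= 2.
#' @param estimator `"plugin"` (maximum-likelihood plug-in) or
#'   `"miller_madow"` (plug-in with Miller-Madow bias correction, clamped
#'   at zero).
#' @return an `mi_config` list. Log base is 2; MI is reported in bits.
#' @export
mi_config <- function(n_bins = "sqrt_n", estimator = c("plugin", "miller_madow")) {
  estimator <- match.arg(estimator)
  if (!identical(n_bins, "sqrt_n")) {
    if (!is_count(n_bins) || n_bins < 2) stopf("n_bins must be >= 2 or \"sqrt_n\"")
    n_bins <- as.integer(n_bins)
  }
  structure(list(n_bins = n_bins, estimator = estimator), class = "mi_config")
}

resolve_bins <- function(config, n) {
  if (identical(config$n_bins, "sqrt_n")) max(2L, as.integer(floor(sqrt(n))))
  else config$n_bins
}

# Equal-frequency binning; ties broken by original index (stable radix sort).
bin_equal_frequency <- function(x, n_bins) {
  n <- length(x)
  o <- radix_order(x)
  b <- integer(n)
  b[o] <- as.integer(floor((seq_len(n) - 1) * n_bins / n)) + 1L
  b
}

#' Plug-in mutual information of a joint contingency table
#'
#' Direct evaluation of `sum p(i,j) log2(p(i,j) / (p(i) p(j)))` over the
#' table, optionally with the Miller-Madow correction
#' `((m_x - 1) + (m_y - 1) - (m_xy - 1)) / (2 N ln 2)` (m = occupied bins),
#' clamped at zero.
#'
#' @param counts non-negative integer matrix of joint bin counts.
#' @param estimator `"plugin"` or `"miller_madow"`.
#' @return MI in bits (non-negative).
#' @examples
#' mi_from_counts(matrix(c(2, 0, 0, 2), 2))  # 1 bit
#' mi_from_counts(matrix(c(1, 1, 1, 1), 2))  # 0 bits
#' @export
mi_from_counts <- function(counts, estimator = c("plugin", "miller_madow")) {
  estimator <- match.arg(estimator)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("negative joint counts")
  n <- sum(counts)
  if (n == 0) stopf("empty contingency table")
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- which(p > 0)
  ratio <- p[nz] / (outer(px, py)[nz])
  mi <- sum(p[nz] * log2(ratio))
  if (estimator == "miller_madow") {
    mx <- sum(px > 0); my <- sum(py > 0); mxy <- length(nz)
    mi <- mi + ((mx - 1) + (my - 1) - (mxy - 1)) / (2 * n * log(2))
  }
  max(0, mi)
}

#' Mutual information between two expression profiles
#'
#' Each vector is discretized by deterministic equal-frequency binning into
#' B bins (`B = floor(sqrt(n))` under the default config) and the plug-in MI
#' of the joint table is returned, in bits. Symmetric in its arguments.
#' A constant vector carries no information: the result is 0, with a warning.
#'
#' @param x,y numeric vectors of equal length (at least 8).
#' @param config an [mi_config()].
#' @return non-negative MI in bits.
#' @export
mutual_information <- function(x, y, config = mi_config()) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 8L) stopf("at least 8 paired observations required")
  if (max(x) == min(x) || max(y) == min(y)) {
    warnf("constant vector: mutual information set to 0")
    return(0)
  }
  B <- resolve_bins(config, n)
  bx <- bin_equal_frequency(x, B)
  by <- bin_equal_frequency(y, B)
  joint <- matrix(tabulate((bx - 1L) * B + by, B * B), nrow = B, byrow = TRUE)
  mi_from_counts(joint, config$estimator)
}

#' All-pairs MI ranked edge list
#'
#' Computes MI for every gene pair of the matrix (optionally restricted to a
#' sample subset, e.g. one phenotype) and returns the canonical ranked edge
#' list. Identical, pair by pair, to calling [mutual_information()]; the
#' joint tables for all pairs are accumulated with per-bin indicator
#' cross-products so the computation is a handful of dense matrix products.
#' Constant genes get MI 0 against every partner.
#'
#' @param normalized genes-by-samples matrix (any monotone scale; MI is
#'   rank-invariant).
#' @param samples optional character vector of sample identifiers to use.
#' @param config an [mi_config()].
#' @return an [mi_edges()] ranked edge list with `choose(n_genes, 2)` rows.
#' @export
mi_matrix <- function(normalized, samples = NULL, config = mi_config()) {
  validate_expression(normalized, "normalized matrix")
  m <- if (is.null(samples)) normalized else {
    missing <- setdiff(samples, colnames(normalized))
    if (length(missing) > 0) stopf("unknown sample '%s'", missing[1])
    normalized[, samples, drop = FALSE]
  }
  n <- ncol(m)
  if (n < 8L) stopf("at least 8 samples required")
  G <- nrow(m)
  if (G < 2L) stopf("at least 2 genes required")
  B <- resolve_bins(config, n)
  constant <- apply(m, 1, function(r) max(r) == min(r))
  codes <- t(apply(m, 1, bin_equal_frequency, n_bins = B))

  ind <- lapply(seq_len(B), function(a) {
    ia <- codes == a
    storage.mode(ia) <- "double"
    ia
  })
  marg <- vapply(ind, rowSums, numeric(G))            # G x B bin occupancies
  lmarg <- log2(pmax(marg, 1))
  acc <- matrix(0, G, G)
  log2n <- log2(n)
  for (a in seq_len(B)) {
    for (b in seq_len(B)) {
      J <- tcrossprod(ind[[a]], ind[[b]])
      lj <- J
      pos <- J > 0
      lj[pos] <- log2(J[pos])
      lj[!pos] <- 0
      term <- J * (lj + log2n - lmarg[, a])
      term <- term - sweep(J, 2, lmarg[, b], "*")
      acc <- acc + term
    }
  }
  mi <- acc / n
  mi <- (mi + t(mi)) / 2
  if (config$estimator == "miller_madow") {
    # per-pair correction needs occupied-cell counts; recompute cheaply
    nz <- matrix(0, G, G)
    for (a in seq_len(B)) for (b in seq_len(B))
      nz <- nz + (tcrossprod(ind[[a]], ind[[b]]) > 0)
    mocc <- rowSums(marg > 0)
    corr <- (outer(mocc - 1, mocc - 1, "+") - (nz - 1)) / (2 * n * log(2))
    mi <- mi + corr
  }
  mi[mi < 0] <- 0
  if (any(constant)) { mi[constant, ] <- 0; mi[, constant] <- 0 }

  ut <- which(upper.tri(mi), arr.ind = TRUE)
  mi_edges(rownames(m)[ut[, 1]], rownames(m)[ut[, 2]], mi[ut])
}

#' Data-processing-inequality pruning
#'
#' For every triangle of genes, the weakest edge is marked for removal when
#' its MI is strictly below `(1 - tolerance)` times the smaller of the other
#' two MI values; all marked edges are removed simultaneously after every
#' triangle has been scanned (so removal never cascades within a pass).
#' Edges not part of any triangle are always kept.
#'
#' @param edges an [mi_edges()] edge list.
#' @param tolerance real in \[0, 1); 0 reproduces the strict rule.
#' @return the pruned [mi_edges()] edge list.
#' @export
dpi_prune <- function(edges, tolerance = 0) {
  stopifnot(inherits(edges, "mi_edges"))
  if (!is.numeric(tolerance) || tolerance < 0 || tolerance >= 1)
    stopf("tolerance must be in [0, 1)")
  if (nrow(edges) < 3L) return(edges)
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  tri <- matrix(igraph::triangles(g), nrow = 3)
  if (ncol(tri) == 0L) return(edges)
  eid <- function(u, v) igraph::get_edge_ids(g, rbind(u, v))
  e12 <- eid(tri[1, ], tri[2, ])
  e13 <- eid(tri[1, ], tri[3, ])
  e23 <- eid(tri[2, ], tri[3, ])
  # graph_from_data_frame preserves row order, so edge id == row index
  w <- edges$mi
  W <- rbind(w[e12], w[e13], w[e23])
  E <- rbind(e12, e13, e23)
  wmin <- apply(W, 2, min)
  wmid <- apply(W, 2, function(col) sort(col)[2])
  kill <- wmin < (1 - tolerance) * wmid
  if (!any(kill)) return(edges)
  victims <- unique(vapply(which(kill), function(j) E[which.min(W[, j]), j],
                           numeric(1)))
  out <- edges[-victims, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mi_edges", "data.frame")
  out
}
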