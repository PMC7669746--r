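# Community detection on (sub)networks and per-community hypergeometric
# over-representation against user-supplied gene sets.

#' Detect communities in a network
#'
#' Partitions the network's nodes with Infomap (default, 10 trials,
#' two-level) or label propagation, both run on MI edge weights when
#' present. The partition is deterministic given `(method, seed)`.
#' Communities never span disconnected components: any community returned by
#' the underlying algorithm that crosses components is split along them.
#' Community ids are contiguous integers from 0, assigned in order of first
#' appearance over the lexicographically sorted node list.
#'
#' @param network an `annotated_network` (from [classify_edges()]) or an
#'   [mi_edges()] edge list.
#' @param method `"infomap"` or `"label_propagation"`.
#' @param seed integer seed (mandatory: both methods are stochastic).
#' @return named integer vector of class `community_partition`
#'   (node -> community id).
#' @export
detect_communities <- function(network,
                               method = c("infomap", "label_propagation"),
                               seed) {
  method <- match.arg(method)
  if (missing(seed) || !is.numeric(seed)) stopf("an integer seed is required")
  edges <- if (inherits(network, "annotated_network")) network$edges else as.data.frame(network)
  if (nrow(edges) == 0L) stopf("detect_communities: network has no edges")
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)), method = "radix")
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  w <- if ("mi" %in% names(edges)) edges$mi else NULL
  if (!is.null(w) && any(w <= 0)) w <- NULL  # zero weights break both methods
  set.seed(as.integer(seed))
  cm <- switch(method,
    infomap = igraph::cluster_infomap(g, e.weights = w, nb.trials = 10),
    label_propagation = igraph::cluster_label_prop(g, weights = w))
  raw <- igraph::membership(cm)
  comp <- igraph::components(g)$membership
  combo <- stats::setNames(paste(raw, comp), igraph::V(g)$name)
  combo <- combo[nodes]  # split communities crossing components; id order fixed
  ids <- as.integer(factor(combo, levels = unique(combo))) - 1L
  structure(stats::setNames(ids, nodes), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d nodes in %d communities\n",
              length(x), length(unique(x))))
  print(sort(table(unclass(x)), decreasing = TRUE))
  invisible(x)
}

#' Hypergeometric over-representation of gene sets in communities
#'
#' For every community of at least `min_community` genes (after intersecting
#' with the universe) and every gene set, computes the upper-tail
#' hypergeometric probability of observing at least the actual overlap:
#' `P(X >= k)` with `K` set genes among `N` universe genes and a community
#' of size `n`. Benjamini-Hochberg adjustment is applied across all tested
#' (community, set) pairs; rows are sorted by FDR.
#'
#' @param partition a [detect_communities()] result.
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]);
#'   members outside the universe are ignored.
#' @param universe character vector: the measured gene background (typically
#'   all genes surviving the mean filter).
#' @param alpha FDR level used for the `significant` flag (default 0.05).
#' @param min_community smallest community size tested (default 5).
#' @return data.frame of class `enrichment_result`: community, set, k, K,
#'   n, N, p_value, fdr, significant.
#' @export
enrich <- function(partition, gene_sets, universe, alpha = 0.05,
                   min_community = 5L) {
  stopifnot(inherits(partition, "community_partition"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stopf("empty universe")
  outside <- setdiff(names(partition), universe)
  if (length(outside) > 0) {
    warnf("%d community gene(s) absent from the universe were dropped", length(outside))
    partition <- partition[!names(partition) %in% outside]
  }
  N <- length(universe)
  comms <- split(names(partition), unclass(partition))
  comms <- comms[lengths(comms) >= min_community]
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  rows <- list()
  for (ci in names(comms)) {
    genes <- comms[[ci]]
    n <- length(genes)
    for (si in names(sets)) {
      K <- length(sets[[si]])
      k <- length(intersect(genes, sets[[si]]))
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        community = as.integer(ci), set = si, k = k, K = K, n = n, N = N,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(structure(data.frame(community = integer(0), set = character(0),
                                k = integer(0), K = integer(0), n = integer(0),
                                N = integer(0), p_value = numeric(0),
                                fdr = numeric(0), significant = logical(0)),
                     class = c("enrichment_result", "data.frame")))
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < alpha
  out <- out[order(out$fdr, out$p_value, out$community, out$set, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
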