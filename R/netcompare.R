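# Edge-set algebra across phenotype networks: Venn regions, pairwise
# sharing, and their behavior across top-N cut-offs. Edges are compared as
# unordered canonical gene-ID pairs; MI values play no role in membership.

#' Multi-network edge intersection
#'
#' Exact set algebra over the canonical edge pairs of two or more named
#' networks: edges shared by all networks, edges specific to exactly one
#' network, pairwise shared counts, the full Venn region sizes, and — when a
#' control network is designated — the "cancer-only" set present in every
#' non-control network and absent from control.
#'
#' @param networks named list; each element an [mi_edges()] edge list (or a
#'   data.frame with `gene_a`, `gene_b`).
#' @param control_name optional name of the control network.
#' @return list of class `intersection_result`: `totals`, `shared_all`,
#'   `group_specific`, `pairwise_shared`, `regions` (membership-pattern
#'   sizes), and `cancer_only` (NULL when no control is designated).
#'   Edge sets are data.frames with columns `gene_a`, `gene_b`.
#' @export
intersect_networks <- function(networks, control_name = NULL) {
  if (length(networks) < 2L) stopf("at least 2 networks required")
  if (is.null(names(networks)) || anyDuplicated(names(networks)))
    stopf("networks must be uniquely named")
  if (!is.null(control_name) && !control_name %in% names(networks))
    stopf("unknown control network '%s'", control_name)
  keys <- lapply(networks, edge_keys)
  universe <- unique(unlist(keys, use.names = FALSE))
  memb <- vapply(keys, function(k) universe %in% k,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, names(networks)))
  n_in <- rowSums(memb)
  shared_all <- universe[n_in == length(networks)]
  specific <- lapply(names(networks), function(nm)
    key_to_pair(universe[memb[, nm] & n_in == 1L]))
  names(specific) <- names(networks)
  pw <- list()
  nms <- names(networks)
  for (i in seq_len(length(nms) - 1L)) for (j in seq(i + 1L, length(nms))) {
    pw[[sprintf("%s|%s", nms[i], nms[j])]] <-
      sum(memb[, nms[i]] & memb[, nms[j]])
  }
  pattern <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  regions <- table(pattern)
  cancer_only <- NULL
  if (!is.null(control_name)) {
    tumor <- setdiff(nms, control_name)
    in_all_tumor <- rowSums(memb[, tumor, drop = FALSE]) == length(tumor)
    cancer_only <- key_to_pair(universe[in_all_tumor & !memb[, control_name]])
  }
  structure(list(
    totals = vapply(keys, length, integer(1)),
    shared_all = key_to_pair(shared_all),
    group_specific = specific,
    pairwise_shared = unlist(pw),
    regions = regions,
    cancer_only = cancer_only,
    control_name = control_name),
    class = "intersection_result")
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf("Intersection of %d networks (totals: %s)\n",
              length(x$totals),
              paste(sprintf("%s=%d", names(x$totals), x$totals), collapse = ", ")))
  cat(sprintf("  shared by all: %d edges\n", nrow(x$shared_all)))
  if (!is.null(x$cancer_only))
    cat(sprintf("  in all non-control, absent from %s: %d edges\n",
                x$control_name, nrow(x$cancer_only)))
  invisible(x)
}

#' Intersection proportions across top-N cut-offs
#'
#' For each cut-off n, truncates every ranked list to its top-n edges, runs
#' [intersect_networks()], and reports `|shared_all| / n` and (with a
#' control) `|cancer_only| / n`.
#'
#' @param ranked named list of [mi_edges()] ranked edge lists.
#' @param cutoffs strictly increasing integer cut-offs.
#' @param control_name optional control network name.
#' @return data.frame of class `cutoff_curve`: cutoff, n_shared_all,
#'   proportion_shared_all, n_cancer_only, proportion_cancer_only.
#' @export
intersection_curve <- function(ranked, cutoffs, control_name = NULL) {
  if (is.unsorted(cutoffs, strictly = TRUE))
    stopf("cutoffs must be strictly increasing")
  rows <- lapply(cutoffs, function(n) {
    res <- intersect_networks(lapply(ranked, top_n, n = n), control_name)
    data.frame(cutoff = n,
               n_shared_all = nrow(res$shared_all),
               proportion_shared_all = nrow(res$shared_all) / n,
               n_cancer_only = if (is.null(res$cancer_only)) NA_integer_ else nrow(res$cancer_only),
               proportion_cancer_only = if (is.null(res$cancer_only)) NA_real_ else nrow(res$cancer_only) / n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_curve", "data.frame")
  out
}

#' Divergence between two equal-size edge sets
#'
#' `1 - |a intersect b| / |a|`: 0 for identical sets, 1 for disjoint ones.
#' The two sets must have the same size (use the same top-n on both).
#'
#' @param a,b edge lists or edge-key vectors of equal size.
#' @return real in \[0, 1\].
#' @export
pairwise_divergence <- function(a, b) {
  ka <- edge_keys(a)
  kb <- edge_keys(b)
  if (length(ka) != length(kb))
    stopf("edge sets differ in size (%d vs %d); apply the same top-n first",
          length(ka), length(kb))
  if (length(ka) == 0L) return(0)
  1 - length(intersect(ka, kb)) / length(ka)
}
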