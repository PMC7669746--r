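# Chromosomal (cis/trans) topology of co-expression networks: edge
# classification, cis-rate statistics, degree distributions, power-law fits,
# connected components.

#' Classify network edges as cis or trans
#'
#' An edge is cis when both endpoints carry the same chromosome label
#' (after stripping an optional "chr" prefix and case-folding, so UCSC and
#' GENCODE dialects compare equal), trans otherwise. Every endpoint must be
#' annotated.
#'
#' @param edges an [mi_edges()] edge list (or a data.frame with `gene_a`,
#'   `gene_b` and optionally `mi`).
#' @param annotation named character vector: chromosome per gene.
#' @return an `annotated_network`: list with `edges` (edge data.frame plus a
#'   `type` column in `{"cis", "trans"}`), `nodes` and the backing
#'   `annotation`.
#' @export
classify_edges <- function(edges, annotation) {
  df <- as.data.frame(edges)
  nodes <- sort(unique(c(df$gene_a, df$gene_b)), method = "radix")
  missing <- setdiff(nodes, names(annotation))
  if (length(missing) > 0)
    stopf("unannotated gene%s: %s",
          if (length(missing) > 1) "s" else "",
          paste(utils::head(missing, 5), collapse = ", "))
  ca <- normalize_chrom(annotation[df$gene_a])
  cb <- normalize_chrom(annotation[df$gene_b])
  df$type <- ifelse(ca == cb, "cis", "trans")
  structure(list(edges = df, nodes = nodes,
                 annotation = annotation[names(annotation) %in% nodes]),
            class = "annotated_network")
}

#' @export
print.annotated_network <- function(x, ...) {
  cat(sprintf("Annotated network: %d nodes, %d edges (%d cis / %d trans)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$type == "cis"), sum(x$edges$type == "trans")))
  invisible(x)
}

#' Cis/trans summary of a classified network
#'
#' Counts cis and trans edges globally and per chromosome. The per-chromosome
#' cis rate is the number of cis edges on that chromosome divided by the
#' number of that chromosome's genes present in the network (so it can
#' exceed 1 on densely wired chromosomes); the whole-network
#' `cis_fraction = n_cis / (n_cis + n_trans)` is reported alongside.
#'
#' @param network an `annotated_network` from [classify_edges()].
#' @return list of class `cis_trans_summary` with `n_cis`, `n_trans`,
#'   `cis_fraction` and `per_chromosome` (data.frame: chromosome, cis_edges,
#'   genes_in_network, cis_rate).
#' @export
cis_trans_summary <- function(network) {
  stopifnot(inherits(network, "annotated_network"))
  edges <- network$edges
  n_cis <- sum(edges$type == "cis")
  n_trans <- sum(edges$type == "trans")
  chrom_of <- normalize_chrom(network$annotation[network$nodes])
  chroms <- sort(unique(chrom_of), method = "radix")
  cis_edges <- edges[edges$type == "cis", , drop = FALSE]
  cis_chrom <- normalize_chrom(network$annotation[cis_edges$gene_a])
  per <- data.frame(
    chromosome = chroms,
    cis_edges = as.integer(vapply(chroms, function(cc) sum(cis_chrom == cc), numeric(1))),
    genes_in_network = as.integer(vapply(chroms, function(cc) sum(chrom_of == cc), numeric(1))),
    stringsAsFactors = FALSE)
  per$cis_rate <- per$cis_edges / per$genes_in_network
  structure(list(n_cis = n_cis, n_trans = n_trans,
                 cis_fraction = if (n_cis + n_trans > 0) n_cis / (n_cis + n_trans) else NA_real_,
                 per_chromosome = per),
            class = "cis_trans_summary")
}

#' @export
print.cis_trans_summary <- function(x, ...) {
  cat(sprintf("cis/trans summary: %d cis, %d trans (cis fraction %.3f)\n",
              x$n_cis, x$n_trans, x$cis_fraction))
  print(x$per_chromosome)
  invisible(x)
}

#' Empirical degree distribution
#'
#' Degrees of all nodes appearing in the edge list (an edge-defined network
#' has no degree-zero nodes); probabilities sum to 1.
#'
#' @param network an `annotated_network` or an edge list.
#' @return data.frame of class `degree_distribution` with columns `k`
#'   (degree) and `p` (empirical probability).
#' @export
degree_distribution <- function(network) {
  edges <- if (inherits(network, "annotated_network")) network$edges else as.data.frame(network)
  if (nrow(edges) == 0L) stopf("degree_distribution: network has no edges")
  deg <- table(c(edges$gene_a, edges$gene_b))
  tab <- table(as.integer(deg))
  out <- data.frame(k = as.integer(names(tab)),
                    p = as.numeric(tab) / length(deg))
  class(out) <- c("degree_distribution", "data.frame")
  out
}

#' Fit a power law y = a * k^b to a degree distribution
#'
#' Nonlinear least squares on the (k, p(k)) points on the linear scale,
#' initialized from the log-log ordinary-least-squares solution;
#' `correlation` is the Pearson correlation between fitted and observed
#' values and `r_square = 1 - SS_res / SS_tot`. Accepts either normalized
#' probabilities or raw counts as the y values.
#'
#' @param dist a [degree_distribution()] (or data.frame with columns `k`, `p`).
#' @return list of class `power_law_fit`: `a`, `b`, `correlation`, `r_square`.
#' @export
fit_power_law <- function(dist) {
  k <- as.numeric(dist$k)
  p <- as.numeric(dist$p)
  if (length(unique(k)) < 3L) stopf("fit_power_law: at least 3 distinct degrees required")
  if (any(k <= 0) || any(p <= 0)) stopf("fit_power_law: k and p must be positive")
  ols <- stats::lm(log(p) ~ log(k))
  a0 <- exp(unname(stats::coef(ols)[1]))
  b0 <- unname(stats::coef(ols)[2])
  if (sum((p - a0 * k^b0)^2) <= 1e-24 * sum(p^2)) {
    # the log-log solution already interpolates the points (noiseless data);
    # refining a zero-residual start is numerically ill-posed
    est <- c(a = a0, b = b0)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(p ~ a * k^b, start = list(a = a0, b = b0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e)
        stopf("power-law fit did not converge (%s); log-log fallback: a=%.6g, b=%.6g",
              conditionMessage(e), a0, b0))
    est <- stats::coef(fit)
  }
  fitted_p <- est[["a"]] * k^est[["b"]]
  ss_res <- sum((p - fitted_p)^2)
  ss_tot <- sum((p - mean(p))^2)
  corr <- if (stats::sd(fitted_p) > 0 && stats::sd(p) > 0)
    stats::cor(fitted_p, p) else NA_real_
  structure(list(a = est[["a"]], b = est[["b"]],
                 correlation = corr,
                 r_square = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law y = a*k^b: a = %.4g, b = %.4g (correlation %.3f, R-square %.3f)\n",
              x$a, x$b, x$correlation, x$r_square))
  invisible(x)
}

#' Largest connected component
#'
#' The maximal connected component by node count; on a tie, the component
#' containing the lexicographically smallest node label wins.
#'
#' @param network an `annotated_network`.
#' @return an `annotated_network` restricted to the component.
#' @export
largest_component <- function(network) {
  stopifnot(inherits(network, "annotated_network"))
  if (length(network$nodes) == 0L) stopf("largest_component: empty network")
  g <- annotated_network_igraph(network)
  comp <- igraph::components(g)
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  if (length(cand) > 1L) {
    # tie: component holding the smallest node label (C locale)
    first_of <- vapply(cand, function(ci) {
      members <- igraph::V(g)$name[comp$membership == ci]
      sort(members, method = "radix")[1]
    }, character(1))
    cand <- cand[radix_order(first_of)[1]]
  }
  keep <- igraph::V(g)$name[comp$membership == cand[1]]
  edges <- network$edges[network$edges$gene_a %in% keep &
                           network$edges$gene_b %in% keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = sort(keep, method = "radix"),
                 annotation = network$annotation[names(network$annotation) %in% keep]),
            class = "annotated_network")
}
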