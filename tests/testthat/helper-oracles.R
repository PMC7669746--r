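# Independent oracles, deliberately written from first principles and kept
# separate from the implementation paths they check.

# Direct plug-in MI of a joint table: sum p log2(p / (p_row p_col)).
oracle_mi_table <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0)
      total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  total
}

# Hand-written trimmed-mean-of-M-values factor of column `obs` against
# column `ref` (unnormalized 2^f; no geometric-mean rescaling).
oracle_tmm_factor <- function(counts, obs, ref,
                              trim_m = 0.30, trim_a = 0.05) {
  x <- counts[, obs]
  y <- counts[, ref]
  n_obs <- sum(x)
  n_ref <- sum(y)
  keep <- x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  m <- log2((x / n_obs) / (y / n_ref))
  a <- (log2(x / n_obs) + log2(y / n_ref)) / 2
  v <- (n_obs - x) / (n_obs * x) + (n_ref - y) / (n_ref * y)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm <- rank(m); ra <- rank(a)
  sel <- rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a
  2^(sum(m[sel] / v[sel]) / sum(1 / v[sel]))
}

# Brute-force DPI: enumerate every node triple; in each full triangle mark
# the weakest edge when strictly below (1 - tol) * min(other two).
oracle_dpi <- function(edges, tolerance = 0) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  w <- stats::setNames(edges$mi, key(edges$gene_a, edges$gene_b))
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  marked <- character(0)
  if (length(nodes) >= 3) {
    trips <- utils::combn(nodes, 3)
    for (t in seq_len(ncol(trips))) {
      ks <- c(key(trips[1, t], trips[2, t]),
              key(trips[1, t], trips[3, t]),
              key(trips[2, t], trips[3, t]))
      if (!all(ks %in% names(w))) next
      ws <- w[ks]
      weakest <- which.min(ws)
      if (ws[weakest] < (1 - tolerance) * min(ws[-weakest]))
        marked <- c(marked, ks[weakest])
    }
  }
  keep <- !(key(edges$gene_a, edges$gene_b) %in% marked)
  edges[keep, , drop = FALSE]
}

# Benjamini-Hochberg closed form: adj_i = min_{j >= i} (m * p_(j) / j),
# mapped back to the input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(m * ps / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= k) by direct enumeration.
oracle_hyper_upper <- function(k, K, N, n) {
  i <- seq(max(0, k), min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Spearman's rho for tie-free vectors: 1 - 6 sum d^2 / (n (n^2 - 1)).
oracle_spearman <- function(a, b) {
  d <- rank(a) - rank(b)
  n <- length(a)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Venn regions via a per-edge membership bitmask over the edge universe.
# Returns a named vector: pattern string (e.g. "10110") -> region size.
oracle_regions <- function(key_sets) {
  universe <- unique(unlist(key_sets))
  pattern <- vapply(universe, function(k)
    paste(vapply(key_sets, function(s) as.integer(k %in% s), integer(1)),
          collapse = ""), character(1))
  tab <- table(pattern)
  stats::setNames(as.integer(tab), names(tab))
}

# Best 2-partition by Newman modularity, exhaustively over all splits.
oracle_best_bipartition <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- length(nodes)
  m <- nrow(edges)
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = nodes))
  best_q <- -Inf
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    side <- c(as.integer(intToBits(mask))[seq_len(n - 1)], 0L)
    q <- 0
    for (e in seq_len(m)) {
      i <- match(edges$gene_a[e], nodes)
      j <- match(edges$gene_b[e], nodes)
      if (side[i] == side[j]) q <- q + 1 / m
    }
    for (s in 0:1) {
      ds <- sum(deg[side == s])
      q <- q - (ds / (2 * m))^2
    }
    if (q > best_q) { best_q <- q; best <- side }
  }
  stats::setNames(best, nodes)
}
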