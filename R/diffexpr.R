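# Differential expression on log2-normalized values: per-stage contrasts vs
# control, all-pairs multi-group contrasts, rank-correlation of signatures,
# and progressive-gene detection across ordered phenotypes.

de_contrast <- function(normalized, samples_contrast, samples_baseline,
                        lfc_threshold, alpha) {
  a <- normalized[, samples_contrast, drop = FALSE]
  b <- normalized[, samples_baseline, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stopf("each group needs at least 2 samples")
  lfc <- rowMeans(a) - rowMeans(b)
  p <- vapply(seq_len(nrow(a)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate: no within-group variance; decided by the mean difference
      return(if (lfc[i] == 0) 1 else 0)
    }
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  p[is.na(p)] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  status <- rep("ns", length(lfc))
  status[lfc > lfc_threshold & fdr < alpha] <- "over"
  status[lfc < -lfc_threshold & fdr < alpha] <- "under"
  out <- data.frame(gene = rownames(normalized), lfc = unname(lfc),
                    p_value = p, fdr = fdr, status = status,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Differential expression of one phenotype against control
#'
#' Per-gene log2 fold change (contrast group mean minus control mean on the
#' log2 scale), two-sided Welch t-test p-values, Benjamini-Hochberg FDR
#' across all genes, and a status call: `over` when
#' `lfc > lfc_threshold & fdr < alpha`, `under` for the mirrored condition,
#' `ns` otherwise.
#'
#' @param normalized log2-scale genes-by-samples matrix.
#' @param labels a [stage_labels()] object.
#' @param contrast_phenotype phenotype compared against the control.
#' @param lfc_threshold absolute log2 fold-change cut-off (default 2.0).
#' @param alpha FDR significance level (default 0.05).
#' @return a `de_result` data.frame: gene, lfc, p_value, fdr, status.
#' @export
differential_expression <- function(normalized, labels, contrast_phenotype,
                                    lfc_threshold = 2.0, alpha = 0.05) {
  stopifnot(inherits(labels, "stage_labels"))
  if (!contrast_phenotype %in% labels$phenotype)
    stopf("contrast phenotype '%s' has no samples", contrast_phenotype)
  de_contrast(normalized,
              label_samples(labels, contrast_phenotype),
              label_samples(labels, attr(labels, "control")),
              lfc_threshold, alpha)
}

#' All unordered phenotype-pair contrasts
#'
#' Runs the machinery of [differential_expression()] for every unordered
#' phenotype pair with a relaxed fold-change threshold (default 0.5,
#' suited to between-stage contrasts); BH is applied within each contrast.
#' For a pair `(a, b)` with `a` earlier in the phenotype order, the reported
#' `lfc` is mean(b) − mean(a).
#'
#' @inheritParams differential_expression
#' @param lfc_threshold absolute log2 fold-change cut-off (default 0.5).
#' @return named list of `de_result` objects, names `"<b>_vs_<a>"`.
#' @export
multi_group_contrasts <- function(normalized, labels, lfc_threshold = 0.5,
                                  alpha = 0.05) {
  stopifnot(inherits(labels, "stage_labels"))
  phen <- attr(labels, "phenotype_order")
  if (length(phen) < 2L) stopf("at least 2 phenotypes required")
  out <- list()
  for (i in seq_len(length(phen) - 1L)) {
    for (j in seq(i + 1L, length(phen))) {
      nm <- sprintf("%s_vs_%s", phen[j], phen[i])
      out[[nm]] <- de_contrast(normalized,
                               label_samples(labels, phen[j]),
                               label_samples(labels, phen[i]),
                               lfc_threshold, alpha)
    }
  }
  out
}

#' Spearman rank correlation of two DE signatures
#'
#' Spearman correlation (average ranks on ties) of the log2 fold-change
#' vectors over the shared gene universe.
#'
#' @param de_a,de_b `de_result` objects.
#' @return correlation in \[-1, 1\].
#' @export
rank_correlation <- function(de_a, de_b) {
  shared <- intersect(de_a$gene, de_b$gene)
  if (length(shared) < 3L) stopf("fewer than 3 shared genes")
  la <- de_a$lfc[match(shared, de_a$gene)]
  lb <- de_b$lfc[match(shared, de_b$gene)]
  stats::cor(la, lb, method = "spearman")
}

#' Detect progressive genes across ordered phenotypes
#'
#' A gene is progressive when its per-phenotype means are strictly monotone
#' over the full phenotype order AND every consecutive phenotype pair
#' differs by a two-sided Wilcoxon rank-sum test, significant after
#' Benjamini-Hochberg adjustment across all genes x consecutive pairs.
#'
#' @param normalized log2-scale genes-by-samples matrix.
#' @param labels a [stage_labels()] object.
#' @param ordered_phenotypes phenotype labels in progression order
#'   (length >= 3), each with at least 2 samples.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.frame of class `progressive_genes`: gene, direction,
#'   one `mean_<phenotype>` column per phenotype, and `max_fdr` (the largest
#'   adjusted p over the gene's consecutive tests).
#' @export
progressive_genes <- function(normalized, labels, ordered_phenotypes,
                              alpha = 0.05) {
  stopifnot(inherits(labels, "stage_labels"))
  if (length(ordered_phenotypes) < 3L)
    stopf("at least 3 ordered phenotypes required")
  if (!all(ordered_phenotypes %in% labels$phenotype))
    stopf("phenotype '%s' has no samples",
          setdiff(ordered_phenotypes, labels$phenotype)[1])
  groups <- lapply(ordered_phenotypes, function(p) label_samples(labels, p))
  if (any(lengths(groups) < 2L))
    stopf("phenotype '%s' has fewer than 2 samples",
          ordered_phenotypes[which(lengths(groups) < 2L)[1]])
  P <- length(groups)
  means <- matrix(
    vapply(groups, function(s) rowMeans(normalized[, s, drop = FALSE]),
           numeric(nrow(normalized))),
    nrow = nrow(normalized))
  diffs <- means[, -1, drop = FALSE] - means[, -P, drop = FALSE]
  up <- apply(diffs > 0, 1, all)
  down <- apply(diffs < 0, 1, all)

  pmat <- matrix(NA_real_, nrow(normalized), P - 1L)
  for (j in seq_len(P - 1L)) {
    xa <- normalized[, groups[[j]], drop = FALSE]
    xb <- normalized[, groups[[j + 1L]], drop = FALSE]
    pmat[, j] <- vapply(seq_len(nrow(normalized)), function(i)
      stats::wilcox.test(xa[i, ], xb[i, ], exact = FALSE)$p.value,
      numeric(1))
  }
  pmat[is.na(pmat)] <- 1  # tied-constant comparisons carry no evidence
  fdr <- matrix(stats::p.adjust(pmat, method = "BH"), nrow(normalized))
  all_sig <- apply(fdr < alpha, 1, all)

  hit <- (up | down) & all_sig
  out <- data.frame(gene = rownames(normalized)[hit],
                    direction = ifelse(up[hit], "up", "down"),
                    stringsAsFactors = FALSE)
  mcols <- as.data.frame(means[hit, , drop = FALSE])
  names(mcols) <- paste0("mean_", ordered_phenotypes)
  out <- cbind(out, mcols, max_fdr = apply(fdr[hit, , drop = FALSE], 1, max))
  rownames(out) <- NULL
  class(out) <- c("progressive_genes", "data.frame")
  out
}
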