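# End-to-end orchestration: simulate (or load) -> preprocess -> DE /
# progressive genes -> per-phenotype MI networks -> cis/trans topology at
# every cut-off -> multi-network intersections -> communities + enrichment.
# Every artifact is a plain-text file under the run directory, and a
# manifest records the config, seed and md5 of every output so a rerun with
# the same config is verifiably identical.

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config()] to simulate the cohort, or NULL
#'   to read `counts_path`/`annotation_path`/`labels_path`.
#' @param counts_path,annotation_path,labels_path input TSVs (ignored when
#'   `synthetic` is given).
#' @param control control phenotype label (taken from `synthetic` when given).
#' @param phenotype_order phenotype labels in progression order.
#' @param min_mean strict mean filter threshold (default 10).
#' @param lfc_threshold per-stage-vs-control log2 fold-change cut-off (default 2.0).
#' @param multi_lfc_threshold between-stage cut-off (default 0.5).
#' @param alpha FDR level for DE, progressive and enrichment calls (default 0.05).
#' @param cutoffs ascending top-N network cut-offs.
#' @param mi an [mi_config()].
#' @param community_method `"infomap"` or `"label_propagation"`.
#' @param gmt_path optional GMT of gene sets for enrichment; when simulating,
#'   the planted modules are written as the gene-set collection by default.
#' @param seed integer seed governing simulation and community detection.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL,
                            counts_path = NULL, annotation_path = NULL,
                            labels_path = NULL,
                            control = "control",
                            phenotype_order = NULL,
                            min_mean = 10, lfc_threshold = 2.0,
                            multi_lfc_threshold = 0.5, alpha = 0.05,
                            cutoffs = c(100L, 1000L, 10000L, 100000L, 1000000L),
                            mi = mi_config(),
                            community_method = "infomap",
                            gmt_path = NULL,
                            seed = 1L) {
  if (is.null(synthetic) &&
      (is.null(counts_path) || is.null(annotation_path) || is.null(labels_path)))
    stopf("either a synthetic config or all three input paths are required")
  if (any(c(min_mean, lfc_threshold, multi_lfc_threshold, alpha) <= 0))
    stopf("thresholds must be positive")
  if (is.unsorted(cutoffs, strictly = TRUE))
    stopf("cutoffs must be strictly ascending")
  structure(list(synthetic = synthetic, counts_path = counts_path,
                 annotation_path = annotation_path, labels_path = labels_path,
                 control = control, phenotype_order = phenotype_order,
                 min_mean = min_mean, lfc_threshold = lfc_threshold,
                 multi_lfc_threshold = multi_lfc_threshold, alpha = alpha,
                 cutoffs = as.integer(cutoffs), mi = mi,
                 community_method = community_method, gmt_path = gmt_path,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields mirror [pipeline_config()] arguments; a `synthetic` block
#' is not supported from YAML (build it in R), so YAML configs always point
#' at input files.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    y[intersect(names(y), c("counts_path", "annotation_path", "labels_path",
                            "control", "phenotype_order", "min_mean",
                            "lfc_threshold", "multi_lfc_threshold", "alpha",
                            "gmt_path", "community_method", "seed"))],
    if (!is.null(y$cutoffs)) list(cutoffs = as.integer(y$cutoffs))))
}

pipeline_log <- function(fmt, ...) message(sprintf(paste0("[stagenet] ", fmt), ...))

#' Run the full stage-wise co-expression analysis
#'
#' Produces, per phenotype: the normalized matrix column subset, a DE table
#' vs control (tumor phenotypes), a ranked MI edge list (truncated at the
#' largest cut-off) and per-cut-off cis/trans summaries with power-law fits.
#' Globally: the rank-correlation matrix between stage signatures, the
#' progressive gene list, intersection results and cut-off curves, the
#' trans-count-vs-cutoff table, the shared-by-all and cancer-only
#' sub-networks with community enrichment, and a `manifest.json` recording
#' package version, config, seed and the md5 of every artifact.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; existing files overwritten).
#' @return `out_dir`, invisibly. Fails with a stage-named error on any
#'   stage failure; artifacts written before the failure are retained.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    pipeline_log("stage %s", name)
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  paths <- character(0)
  emit <- function(name) paths[[length(paths) + 1L]] <<- name

  # --- inputs ---------------------------------------------------------------
  truth <- NULL
  inputs <- stage("input", {
    if (!is.null(config$synthetic)) {
      cohort <- generate_cohort(config$synthetic)
      truth <<- cohort$truth
      write_cohort(cohort, file.path(out_dir, "input"))
      for (f in c("expression.tsv", "annotation.tsv", "labels.tsv", "truth.json"))
        emit(file.path("input", f))
      list(counts = cohort$counts, annotation = cohort$annotation,
           labels = cohort$labels)
    } else {
      lab <- read_labels(config$labels_path, config$control)
      if (!is.null(config$phenotype_order))
        lab <- stage_labels(stats::setNames(lab$phenotype, lab$sample_id),
                            control = config$control,
                            phenotype_order = config$phenotype_order)
      list(counts = read_expression(config$counts_path),
           annotation = read_annotation(config$annotation_path),
           labels = lab)
    }
  })
  labels <- inputs$labels
  phen <- attr(labels, "phenotype_order")
  control <- attr(labels, "control")
  tumors <- setdiff(phen, control)

  # --- preprocess -----------------------------------------------------------
  norm <- stage("preprocess", normalize_counts(inputs$counts, config$min_mean))
  stage("preprocess", {
    write_expression(norm$normalized, file.path(out_dir, "normalized.tsv"))
    emit("normalized.tsv")
    utils::write.table(
      data.frame(sample_id = names(norm$scale_factors),
                 factor = norm$scale_factors),
      file.path(out_dir, "scale_factors.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    emit("scale_factors.tsv")
  })

  # --- differential expression ---------------------------------------------
  de <- stage("diffexpr", {
    de <- lapply(tumors, function(p)
      differential_expression(norm$normalized, labels, p,
                              config$lfc_threshold, config$alpha))
    names(de) <- tumors
    for (p in tumors) {
      f <- sprintf("de_%s.tsv", p)
      utils::write.table(de[[p]], file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(f)
    }
    de
  })
  stage("diffexpr", {
    cors <- outer(tumors, tumors, Vectorize(function(a, b)
      rank_correlation(de[[a]], de[[b]])))
    dimnames(cors) <- list(tumors, tumors)
    utils::write.table(round(cors, 6), file.path(out_dir, "rank_correlations.tsv"),
                       sep = "\t", quote = FALSE)
    emit("rank_correlations.tsv")
    prog <- progressive_genes(norm$normalized, labels, phen, config$alpha)
    utils::write.table(prog, file.path(out_dir, "progressive_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("progressive_genes.tsv")
  })

  # --- network inference ----------------------------------------------------
  max_cut <- max(config$cutoffs)
  ranked <- stage("netinfer", {
    r <- lapply(phen, function(p)
      top_n(mi_matrix(norm$normalized, label_samples(labels, p), config$mi),
            max_cut))
    names(r) <- phen
    for (p in phen) {
      f <- sprintf("edges_%s.tsv", p)
      write_edges(r[[p]], file.path(out_dir, f))
      emit(f)
    }
    r
  })

  # --- topology -------------------------------------------------------------
  topo <- stage("topology", {
    res <- list()
    for (p in phen) {
      net_full <- classify_edges(ranked[[p]], inputs$annotation)
      per_cut <- lapply(config$cutoffs, function(n) {
        net <- classify_edges(top_n(ranked[[p]], n), inputs$annotation)
        s <- cis_trans_summary(net)
        fit <- tryCatch(fit_power_law(degree_distribution(net)),
                        error = function(e) NULL)
        list(cutoff = n, n_cis = s$n_cis, n_trans = s$n_trans,
             cis_fraction = s$cis_fraction,
             power_law = if (is.null(fit)) NULL else unclass(fit))
      })
      summ <- cis_trans_summary(net_full)
      export_graphml(largest_component(net_full), NULL,
                     file.path(out_dir, sprintf("component_%s.graphml", p)))
      emit(sprintf("component_%s.graphml", p))
      res[[p]] <- list(per_cutoff = per_cut,
                       per_chromosome = summ$per_chromosome)
    }
    jsonlite::write_json(res, file.path(out_dir, "topology.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("topology.json")
    res
  })
  trans_tab <- stage("topology", {
    tab <- do.call(rbind, lapply(phen, function(p) data.frame(
      phenotype = p,
      cutoff = config$cutoffs,
      n_trans = vapply(topo[[p]]$per_cutoff, function(x) x$n_trans, numeric(1)),
      n_cis = vapply(topo[[p]]$per_cutoff, function(x) x$n_cis, numeric(1)))))
    utils::write.table(tab, file.path(out_dir, "trans_by_cutoff.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("trans_by_cutoff.tsv")
    tab
  })

  # --- intersections --------------------------------------------------------
  inter <- stage("netcompare", {
    res <- intersect_networks(ranked, control_name = control)
    curve <- intersection_curve(ranked, config$cutoffs, control_name = control)
    utils::write.table(curve, file.path(out_dir, "intersection_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("intersection_curve.tsv")
    for (nm in c("shared_all", "cancer_only")) {
      f <- sprintf("%s_edges.tsv", nm)
      utils::write.table(res[[nm]], file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(f)
    }
    res
  })

  # --- communities / enrichment --------------------------------------------
  enr <- stage("communities", {
    universe <- rownames(norm$normalized)
    sets <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
    else if (!is.null(truth) && length(truth$modules) > 0) {
      s <- lapply(truth$modules, `[[`, "genes")
      write_gmt(s, file.path(out_dir, "planted_sets.gmt"))
      emit("planted_sets.gmt")
      s
    } else NULL
    out <- list()
    for (nm in c("shared_all", "cancer_only")) {
      edges <- inter[[nm]]
      if (is.null(edges) || nrow(edges) == 0 || is.null(sets)) next
      part <- detect_communities(edges, config$community_method,
                                 seed = config$seed)
      res <- enrich(part, sets, universe, config$alpha)
      f <- sprintf("enrichment_%s.tsv", nm)
      utils::write.table(res, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(f)
      out[[nm]] <- res
    }
    out
  })

  # --- manifest -------------------------------------------------------------
  stage("manifest", {
    ctrl_trans <- trans_tab[trans_tab$phenotype == control, "n_trans"]
    tumor_max_trans <- vapply(config$cutoffs, function(n)
      max(trans_tab$n_trans[trans_tab$phenotype != control &
                              trans_tab$cutoff == n]), numeric(1))
    manifest <- list(
      package = "stagenet",
      version = as.character(utils::packageVersion("stagenet")),
      seed = config$seed,
      config = serialize_config(config),
      phenotypes = phen,
      control = control,
      n_shared_all = nrow(inter$shared_all),
      n_cancer_only = nrow(inter$cancer_only),
      control_trans_by_cutoff = ctrl_trans,
      max_tumor_trans_by_cutoff = tumor_max_trans,
      control_trans_exceeds_all_tumors = all(ctrl_trans > tumor_max_trans),
      files = {
        md5 <- tools::md5sum(file.path(out_dir, unlist(paths)))
        stats::setNames(as.list(unname(md5)), unlist(paths))
      })
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  pipeline_log("run complete: %s", out_dir)
  invisible(out_dir)
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$mi <- unclass(out$mi)
  if (!is.null(out$synthetic)) {
    s <- unclass(out$synthetic)
    s$modules <- lapply(s$modules, unclass)
    s$progressive_genes <- lapply(s$progressive_genes, unclass)
    s$samples_per_phenotype <- as.list(s$samples_per_phenotype)
    out$synthetic <- s
  }
  out
}
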