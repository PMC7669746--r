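# Synthetic multi-phenotype RNA-seq cohorts with planted structure.
#
# The generator plants three kinds of ground truth a real stage-wise cohort
# would carry: (1) co-expression modules driven by a shared latent factor,
# active only in chosen phenotypes and optionally constrained to one
# chromosome (cis); (2) progressive genes whose mean changes by an exact
# multiplicative step per consecutive phenotype; (3) negative-binomial count
# noise. Every downstream stage of the pipeline is validated against the
# recorded truth.

# Module genes swing over a 1.5 log2-unit SD — the dynamic range of a
# strongly co-regulated cancer module, and comfortably above the
# count-level noise so planted wiring is identifiable.
module_log2_sd <- function() 1.5

#' Specification of one planted co-expression module
#'
#' A module is a set of genes sharing a latent factor in the phenotypes
#' where it is active. `latent_strength` is the fraction of the log2-scale
#' variance (total SD fixed at 1.5 log2 units) carried by the shared
#' factor; the remainder is independent per-gene log-normal noise, on top
#' of the count-level negative-binomial noise.
#'
#' @param gene_ids integer gene indices (1-based, must fit `n_genes`).
#' @param active_in character vector of phenotypes where the module co-expresses.
#' @param cis_constrained if TRUE, all module genes are placed on a single
#'   chromosome (overriding the round-robin assignment), so every planted
#'   pair is a cis pair.
#' @param latent_strength fraction in (0, 1] of log-variance from the shared factor.
#' @return a `module_spec` list.
#' @export
module_spec <- function(gene_ids, active_in, cis_constrained = FALSE,
                        latent_strength = 0.8) {
  gene_ids <- as.integer(gene_ids)
  if (length(gene_ids) < 2L) stopf("module_spec: gene_ids must contain at least 2 genes")
  if (anyDuplicated(gene_ids)) stopf("module_spec: gene_ids must be unique")
  if (length(active_in) < 1L) stopf("module_spec: active_in must be nonempty")
  if (!is.numeric(latent_strength) || latent_strength <= 0 || latent_strength > 1)
    stopf("module_spec: latent_strength must be in (0, 1]")
  structure(list(gene_ids = gene_ids, active_in = as.character(active_in),
                 cis_constrained = isTRUE(cis_constrained),
                 latent_strength = latent_strength),
            class = "module_spec")
}

#' Specification of one planted progressive gene
#'
#' The gene's expected count is multiplied by `fold_step` (direction `up`)
#' or divided by it (`down`) at every consecutive phenotype, so the monotone
#' ground truth is exact on the mean scale.
#'
#' @param gene_id integer gene index (1-based).
#' @param direction "up" or "down".
#' @param fold_step multiplicative mean change per consecutive phenotype (> 1).
#' @return a `progressive_spec` list.
#' @export
progressive_spec <- function(gene_id, direction = c("up", "down"), fold_step = 2) {
  direction <- match.arg(direction)
  if (!is.numeric(fold_step) || fold_step <= 1)
    stopf("progressive_spec: fold_step must be > 1")
  structure(list(gene_id = as.integer(gene_id), direction = direction,
                 fold_step = fold_step),
            class = "progressive_spec")
}

#' Configuration of a synthetic cohort
#'
#' @param n_genes number of genes.
#' @param n_chromosomes number of chromosomes; genes are assigned round-robin
#'   (gene i on chromosome `((i-1) mod n_chromosomes) + 1`) unless a
#'   cis-constrained module overrides the assignment.
#' @param phenotypes ordered phenotype labels, first one the control.
#' @param samples_per_phenotype named integer vector (one entry per phenotype).
#' @param modules list of [module_spec()] objects.
#' @param progressive_genes list of [progressive_spec()] objects; their gene
#'   indices must be disjoint from all module genes.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param baseline_mean_range per-gene baseline means are drawn log-uniformly
#'   from this range.
#' @param seed integer RNG seed; identical seeds give byte-identical cohorts.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes, n_chromosomes, phenotypes,
                             samples_per_phenotype,
                             modules = list(), progressive_genes = list(),
                             nb_dispersion = 0.1,
                             baseline_mean_range = c(50, 500),
                             seed = 1L) {
  if (!is_count(n_genes)) stopf("invalid config field 'n_genes': positive integer required")
  if (!is_count(n_chromosomes)) stopf("invalid config field 'n_chromosomes': positive integer required")
  phenotypes <- as.character(phenotypes)
  if (length(phenotypes) < 1L || anyDuplicated(phenotypes))
    stopf("invalid config field 'phenotypes': nonempty unique labels required")
  if (is.null(names(samples_per_phenotype)) ||
      !setequal(names(samples_per_phenotype), phenotypes))
    stopf("invalid config field 'samples_per_phenotype': names must equal phenotypes")
  if (!all(vapply(samples_per_phenotype, is_count, logical(1))))
    stopf("invalid config field 'samples_per_phenotype': positive integers required")
  samples_per_phenotype <- vapply(samples_per_phenotype[phenotypes], as.integer, integer(1))
  if (!all(vapply(modules, inherits, logical(1), "module_spec")))
    stopf("invalid config field 'modules': list of module_spec required")
  if (!all(vapply(progressive_genes, inherits, logical(1), "progressive_spec")))
    stopf("invalid config field 'progressive_genes': list of progressive_spec required")
  module_genes <- unlist(lapply(modules, `[[`, "gene_ids"))
  prog_genes <- vapply(progressive_genes, `[[`, integer(1), "gene_id")
  if (length(module_genes) > 0 && any(module_genes > n_genes | module_genes < 1))
    stopf("invalid config field 'modules': gene index out of range 1..%d", n_genes)
  if (length(prog_genes) > 0 && any(prog_genes > n_genes | prog_genes < 1))
    stopf("invalid config field 'progressive_genes': gene index out of range 1..%d", n_genes)
  if (anyDuplicated(prog_genes))
    stopf("invalid config field 'progressive_genes': duplicated gene index")
  if (length(intersect(module_genes, prog_genes)) > 0)
    stopf("invalid config field 'progressive_genes': indices overlap module genes")
  for (m in modules)
    if (!all(m$active_in %in% phenotypes))
      stopf("invalid config field 'modules': active_in phenotype '%s' unknown",
            setdiff(m$active_in, phenotypes)[1])
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stopf("invalid config field 'nb_dispersion': positive real required")
  if (length(baseline_mean_range) != 2L || any(baseline_mean_range <= 0) ||
      baseline_mean_range[1] > baseline_mean_range[2])
    stopf("invalid config field 'baseline_mean_range': increasing positive pair required")
  structure(list(n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 phenotypes = phenotypes,
                 samples_per_phenotype = samples_per_phenotype,
                 modules = modules, progressive_genes = progressive_genes,
                 nb_dispersion = nb_dispersion,
                 baseline_mean_range = baseline_mean_range,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic cohort
#'
#' Draws counts `NB(mu, dispersion)` where the per-gene, per-sample log2 mean
#' is baseline + module latent contribution (shared factor per module, in the
#' phenotypes where the module is active) + progressive offset
#' (`log2(fold_step) * phenotype index * direction sign`). The generator is a
#' pure function of the config: the same seed reproduces the cohort exactly.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `synthetic_cohort` with elements
#'   `counts` (genes x samples integer matrix), `annotation` (named
#'   chromosome vector), `labels` ([stage_labels()]) and `truth`
#'   (ground-truth record; see [expected_cis_fraction()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  phen <- config$phenotypes
  nper <- config$samples_per_phenotype

  gene_ids <- sprintf("g%04d", seq_len(ng))
  chrom <- as.character(((seq_len(ng) - 1L) %% config$n_chromosomes) + 1L)
  for (m in config$modules)
    if (m$cis_constrained) chrom[m$gene_ids] <- chrom[m$gene_ids[1]]
  annotation <- stats::setNames(chrom, gene_ids)

  sample_ids <- unlist(lapply(phen, function(p) sprintf("%s_s%03d", p, seq_len(nper[[p]]))))
  sample_phen <- rep(phen, times = nper[phen])
  labels <- stage_labels(stats::setNames(sample_phen, sample_ids),
                         control = phen[1], phenotype_order = phen)

  baseline <- 2^stats::runif(ng, log2(config$baseline_mean_range[1]),
                             log2(config$baseline_mean_range[2]))
  log2mu <- matrix(rep(log2(baseline), length(sample_ids)),
                   nrow = ng, dimnames = list(gene_ids, sample_ids))

  # Shared-latent module structure: total log2 SD fixed at module_log2_sd;
  # latent_strength splits the variance between the shared factor and
  # independent per-gene noise. Loadings alternate in sign so a module is
  # composition-neutral: its total count barely moves with the factor, as
  # for the small module fractions of a real transcriptome, so library-size
  # normalization stays unbiased. MI between module genes is unaffected
  # (it is blind to correlation sign).
  for (m in config$modules) {
    s_lat <- module_log2_sd() * sqrt(m$latent_strength)
    s_eps <- module_log2_sd() * sqrt(1 - m$latent_strength)
    loading <- rep(c(1, -1), length.out = length(m$gene_ids))
    for (p in phen) {
      if (!p %in% m$active_in) next
      cols <- which(sample_phen == p)
      z <- stats::rnorm(length(cols))
      for (gi in seq_along(m$gene_ids))
        log2mu[m$gene_ids[gi], cols] <- log2mu[m$gene_ids[gi], cols] +
          loading[gi] * s_lat * z + s_eps * stats::rnorm(length(cols))
    }
  }

  phen_index <- stats::setNames(seq_along(phen) - 1L, phen)  # control = 0
  for (pr in config$progressive_genes) {
    sign <- if (pr$direction == "up") 1 else -1
    log2mu[pr$gene_id, ] <- log2mu[pr$gene_id, ] +
      sign * log2(pr$fold_step) * phen_index[sample_phen]
  }

  counts <- matrix(
    stats::rnbinom(length(log2mu), size = 1 / config$nb_dispersion, mu = 2^log2mu),
    nrow = ng, dimnames = dimnames(log2mu))
  storage.mode(counts) <- "double"

  truth <- build_ground_truth(config, gene_ids, annotation)
  structure(list(counts = counts, annotation = annotation, labels = labels,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

build_ground_truth <- function(config, gene_ids, annotation) {
  pairs <- list()
  modules <- list()
  for (i in seq_along(config$modules)) {
    m <- config$modules[[i]]
    mname <- sprintf("module_%02d", i)
    ids <- sort(gene_ids[m$gene_ids])
    modules[[mname]] <- list(genes = ids, active_in = m$active_in,
                             cis_constrained = m$cis_constrained,
                             latent_strength = m$latent_strength)
    cmb <- utils::combn(ids, 2)
    pairs[[mname]] <- data.frame(
      gene_a = cmb[1, ], gene_b = cmb[2, ], module = mname,
      cis = normalize_chrom(annotation[cmb[1, ]]) ==
        normalize_chrom(annotation[cmb[2, ]]),
      stringsAsFactors = FALSE)
  }
  pair_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               module = character(0), cis = logical(0))
  rownames(pair_df) <- NULL
  prog <- if (length(config$progressive_genes)) data.frame(
    gene = gene_ids[vapply(config$progressive_genes, `[[`, integer(1), "gene_id")],
    direction = vapply(config$progressive_genes, `[[`, character(1), "direction"),
    fold_step = vapply(config$progressive_genes, `[[`, numeric(1), "fold_step"),
    stringsAsFactors = FALSE) else
      data.frame(gene = character(0), direction = character(0), fold_step = numeric(0))
  structure(list(modules = modules, pairs = pair_df, progressive = prog,
                 phenotypes = config$phenotypes),
            class = "ground_truth")
}

#' Planted cis fraction of a phenotype's true module pairs
#'
#' Among all planted within-module gene pairs active in `phenotype`, the
#' fraction whose two genes share a chromosome. This is the ground truth the
#' recovered network-level cis fraction is compared against.
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param phenotype phenotype label.
#' @return real in \[0, 1\].
#' @export
expected_cis_fraction <- function(truth, phenotype) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!phenotype %in% truth$phenotypes)
    stopf("unknown phenotype '%s'", phenotype)
  active <- names(Filter(function(m) phenotype %in% m$active_in, truth$modules))
  pairs <- truth$pairs[truth$pairs$module %in% active, , drop = FALSE]
  if (nrow(pairs) == 0L) stopf("no planted pairs for phenotype '%s'", phenotype)
  mean(pairs$cis)
}

#' Write a cohort's standard pipeline inputs to a directory
#'
#' Emits `expression.tsv`, `annotation.tsv`, `labels.tsv` and `truth.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$counts, file.path(dir, "expression.tsv"))
  write_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_labels(cohort$labels, file.path(dir, "labels.tsv"))
  jsonlite::write_json(unclass(cohort$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
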