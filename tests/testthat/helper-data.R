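# Small fixtures built in code at test time.

mk_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# A noise-only miniature cohort: two phenotypes, no planted structure.
tiny_config <- function(seed = 1L, n_genes = 30L, n_per = 10L) {
  synthetic_config(
    n_genes = n_genes, n_chromosomes = 5L,
    phenotypes = c("control", "tumor"),
    samples_per_phenotype = c(control = n_per, tumor = n_per),
    seed = seed)
}

# One cis module + one trans module, both active in the tumor phenotype.
two_module_config <- function(seed = 1L, latent = 0.8, n_per = 60L) {
  synthetic_config(
    n_genes = 30L, n_chromosomes = 5L,
    phenotypes = c("control", "tumor"),
    samples_per_phenotype = c(control = n_per, tumor = n_per),
    modules = list(
      module_spec(1:5, "tumor", cis_constrained = TRUE, latent_strength = latent),
      module_spec(6:10, "tumor", cis_constrained = FALSE, latent_strength = latent)),
    seed = seed)
}

# Random canonical edge keys over a gene universe, as an mi_edges object.
random_edges <- function(n_edges, n_genes, seed) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  all_pairs <- utils::combn(genes, 2)
  pick <- sample(ncol(all_pairs), n_edges)
  mi_edges(all_pairs[1, pick], all_pairs[2, pick], stats::runif(n_edges))
}

mk_de_result <- function(genes, lfc) {
  out <- data.frame(gene = genes, lfc = lfc, p_value = rep(1, length(genes)),
                    fdr = rep(1, length(genes)), status = "ns",
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}
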