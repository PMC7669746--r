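# Canned synthetic study designs.
#
# These fix the conditions under which the pipeline is exercised and
# validated; the methods vignette documents why each design looks the way
# it does. All use five phenotypes (control + four tumor stages), 22
# chromosomes and NB dispersion 0.1 — desk-scale stand-ins for a staged
# bulk RNA-seq cohort.

stage_phenotypes <- function() c("control", "stage_i", "stage_ii", "stage_iii", "stage_iv")

tumor_stages <- function() stage_phenotypes()[-1]

#' Cohort design with opposed cis/trans wiring in control vs tumors
#'
#' Plants a control phenotype whose co-expression is trans-rich (planted cis
#' fraction 0.200) and tumor stages that are cis-rich (planted cis fraction
#' 812/1022 = 0.794, the closest equal-module design fitting 200 genes).
#' Tumor modules: two 29-gene single-chromosome (cis) modules plus one
#' 21-gene module spread over 21 distinct chromosomes (trans). Control:
#' one 21-gene cis module plus four 21-gene trans modules. 60 samples per
#' phenotype, latent strength 0.95 (planted-pair MI must clear the binned
#' estimator's finite-sample chance floor for the wiring to be recoverable).
#'
#' @param seed integer RNG seed.
#' @return a [synthetic_config()].
#' @export
cis_cohort_config <- function(seed = 1L) {
  ls <- 0.95
  tum <- tumor_stages()
  idx <- 0L
  take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }
  modules <- c(
    lapply(1:2, function(i) module_spec(take(29), tum, cis_constrained = TRUE,
                                        latent_strength = ls)),
    list(module_spec(take(21), tum, cis_constrained = FALSE, latent_strength = ls)),
    list(module_spec(take(21), "control", cis_constrained = TRUE, latent_strength = ls)),
    lapply(1:4, function(i) module_spec(take(21), "control", cis_constrained = FALSE,
                                        latent_strength = ls))
  )
  synthetic_config(
    n_genes = 200L, n_chromosomes = 22L, phenotypes = stage_phenotypes(),
    samples_per_phenotype = stats::setNames(rep(60L, 5), stage_phenotypes()),
    modules = modules, seed = seed)
}

#' Cohort design with graded shared plus phenotype-specific modules
#'
#' For intersection-curve behavior: ten 8-gene modules active in every
#' phenotype with latent strengths graded from 0.95 down to 0.60 (so the
#' global MI ranking of shared pairs is roughly consistent across networks,
#' 280 shared pairs in total), four 10-gene tumor-only modules and two
#' 10-gene control-only modules at strength 0.5. As the cut-off grows past
#' the shared pool, the proportion of edges shared by all five networks
#' falls — the multi-scale intersection signature.
#'
#' @param seed integer RNG seed.
#' @return a [synthetic_config()].
#' @export
intersection_cohort_config <- function(seed = 1L) {
  tum <- tumor_stages()
  all_ph <- stage_phenotypes()
  idx <- 0L
  take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }
  shared_strengths <- seq(0.95, 0.60, length.out = 10)
  modules <- c(
    lapply(shared_strengths, function(s)
      module_spec(take(8), all_ph, latent_strength = s)),
    lapply(1:4, function(i) module_spec(take(10), tum, latent_strength = 0.5)),
    lapply(1:2, function(i) module_spec(take(10), "control", latent_strength = 0.5))
  )
  synthetic_config(
    n_genes = 200L, n_chromosomes = 22L, phenotypes = all_ph,
    samples_per_phenotype = stats::setNames(rep(60L, 5), all_ph),
    modules = modules, seed = seed)
}

#' Cohort design with planted monotone progressive genes
#'
#' 120 genes, 60 samples per phenotype; four progressive genes with
#' fold step 2 per consecutive stage (two up, two down — mirroring the
#' two-up/two-down progressive signature a staged tumor series can show),
#' on a background of pure NB noise.
#'
#' @param seed integer RNG seed.
#' @param fold_step multiplicative step per stage.
#' @return a [synthetic_config()].
#' @export
progressive_cohort_config <- function(seed = 1L, fold_step = 2) {
  prog <- list(
    progressive_spec(101L, "up", fold_step),
    progressive_spec(102L, "up", fold_step),
    progressive_spec(103L, "down", fold_step),
    progressive_spec(104L, "down", fold_step)
  )
  synthetic_config(
    n_genes = 120L, n_chromosomes = 22L, phenotypes = stage_phenotypes(),
    samples_per_phenotype = stats::setNames(rep(60L, 5), stage_phenotypes()),
    progressive_genes = prog, seed = seed)
}

#' Demo cohort driving the end-to-end pipeline
#'
#' 200 genes, five phenotypes, 40 samples each. Combines every planted
#' feature: tumor-cis vs control-trans wiring (two 20-gene cis modules and a
#' 12-gene trans module in tumors; mirrored in control), two modules shared
#' by all phenotypes (one cis, one trans), and four progressive genes.
#'
#' @param seed integer RNG seed.
#' @return a [synthetic_config()].
#' @export
demo_config <- function(seed = 1L) {
  tum <- tumor_stages()
  all_ph <- stage_phenotypes()
  ls <- 0.8
  idx <- 0L
  take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }
  modules <- c(
    lapply(1:2, function(i) module_spec(take(20), tum, cis_constrained = TRUE,
                                        latent_strength = ls)),
    list(module_spec(take(12), tum, latent_strength = ls)),
    lapply(1:2, function(i) module_spec(take(20), "control", latent_strength = ls)),
    list(module_spec(take(12), "control", cis_constrained = TRUE, latent_strength = ls)),
    list(module_spec(take(15), all_ph, cis_constrained = TRUE, latent_strength = 0.9)),
    list(module_spec(take(15), all_ph, latent_strength = 0.9))
  )
  prog <- list(
    progressive_spec(idx + 1L, "up", 2), progressive_spec(idx + 2L, "up", 2),
    progressive_spec(idx + 3L, "down", 2), progressive_spec(idx + 4L, "down", 2)
  )
  synthetic_config(
    n_genes = 200L, n_chromosomes = 22L, phenotypes = all_ph,
    samples_per_phenotype = stats::setNames(rep(40L, 5), all_ph),
    modules = modules, progressive_genes = prog, seed = seed)
}
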