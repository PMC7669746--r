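# Synthetic cohort generator: determinism, planted structure, ground truth.

test_that("identical seeds give byte-identical cohorts", {
  cfg <- tiny_config(seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$labels, b$labels)
  c3 <- generate_cohort(tiny_config(seed = 8L))
  expect_false(identical(a$counts, c3$counts))
})

test_that("cis-constrained module genes share one chromosome; others are round-robin", {
  cfg <- two_module_config(seed = 2L)
  co <- generate_cohort(cfg)
  cis_genes <- co$truth$modules$module_01$genes
  expect_length(unique(co$annotation[cis_genes]), 1L)
  # trans module genes 6:10 keep the round-robin assignment over 5 chromosomes
  trans_genes <- co$truth$modules$module_02$genes
  expect_length(unique(co$annotation[trans_genes]), 5L)
  # non-module genes: gene i on chromosome ((i-1) mod 5) + 1
  expect_equal(unname(co$annotation["g0012"]), "2")
})

test_that("config validation errors name the offending field", {
  expect_error(synthetic_config(0, 2, "a", c(a = 3)), "n_genes")
  expect_error(
    synthetic_config(10, 2, c("a", "b"), c(a = 3)),
    "samples_per_phenotype")
  expect_error(
    synthetic_config(10, 2, "a", c(a = 3),
                     modules = list(module_spec(9:11, "a"))),
    "modules")
  expect_error(
    synthetic_config(10, 2, "a", c(a = 3),
                     modules = list(module_spec(1:3, "b"))),
    "active_in")
  expect_error(
    synthetic_config(10, 2, "a", c(a = 3),
                     modules = list(module_spec(1:3, "a")),
                     progressive_genes = list(progressive_spec(2, "up", 2))),
    "overlap")
  expect_error(module_spec(1, "a"), "at least 2")
  expect_error(progressive_spec(1, "up", 1), "fold_step")
})

test_that("an up-progressive gene's sample mean increases with stage in every cohort", {
  # direct-simulation check of the planted monotone ground truth, 20 seeds
  cfg_for <- function(s) synthetic_config(
    n_genes = 20L, n_chromosomes = 3L,
    phenotypes = c("control", "s1", "s2", "s3", "s4"),
    samples_per_phenotype = stats::setNames(rep(30L, 5), c("control", "s1", "s2", "s3", "s4")),
    progressive_genes = list(progressive_spec(5L, "up", 2)),
    seed = s)
  for (s in 1:20) {
    co <- generate_cohort(cfg_for(s))
    means <- tapply(co$counts["g0005", ], co$labels$phenotype, mean)
    means <- means[attr(co$labels, "phenotype_order")]
    expect_true(all(diff(means) > 0), info = sprintf("seed %d", s))
  }
})

test_that("background gene count means match the drawn baseline within 3 SE", {
  cfg <- synthetic_config(
    n_genes = 10L, n_chromosomes = 2L, phenotypes = "only",
    samples_per_phenotype = c(only = 100L), nb_dispersion = 0.1, seed = 3L)
  co <- generate_cohort(cfg)
  # reproduce the baseline draw: it is the first RNG use after the seed
  set.seed(3L)
  baseline <- 2^stats::runif(10, log2(50), log2(500))
  for (g in 1:10) {
    x <- co$counts[g, ]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - baseline[g]), 3 * se + 1e-9)
  }
})

test_that("expected_cis_fraction enumerates planted pairs correctly", {
  # one cis module (3 genes, C(3,2)=3 pairs) + one trans module on 3 chromosomes
  cfg <- synthetic_config(
    n_genes = 12L, n_chromosomes = 3L, phenotypes = "p",
    samples_per_phenotype = c(p = 3L),
    modules = list(
      module_spec(1:3, "p", cis_constrained = TRUE),
      module_spec(4:6, "p", cis_constrained = FALSE)),
    seed = 1L)
  co <- generate_cohort(cfg)
  # genes 4,5,6 sit on chromosomes 1,2,3 by round-robin: all 3 pairs trans
  expect_equal(expected_cis_fraction(co$truth, "p"), 0.5)

  cis_only <- generate_cohort(synthetic_config(
    n_genes = 8L, n_chromosomes = 3L, phenotypes = "p",
    samples_per_phenotype = c(p = 3L),
    modules = list(module_spec(1:5, "p", cis_constrained = TRUE)), seed = 1L))
  expect_equal(expected_cis_fraction(cis_only$truth, "p"), 1.0)

  none <- generate_cohort(synthetic_config(
    n_genes = 8L, n_chromosomes = 3L, phenotypes = "p",
    samples_per_phenotype = c(p = 3L), seed = 1L))
  expect_error(expected_cis_fraction(none$truth, "p"), "no planted pairs")
  expect_error(expected_cis_fraction(co$truth, "nope"), "unknown phenotype")
})

test_that("planted module pairs carry more MI than background pairs where active", {
  hits <- 0L
  for (s in 1:5) {
    co <- generate_cohort(two_module_config(seed = s, latent = 0.6))
    norm <- normalize_counts(co$counts)
    for (ph in c("tumor", "control")) {
      e <- mi_matrix(norm$normalized,
                     co$labels$sample_id[co$labels$phenotype == ph])
      key <- paste(e$gene_a, e$gene_b)
      planted <- key %in% paste(co$truth$pairs$gene_a, co$truth$pairs$gene_b)
      med_planted <- stats::median(e$mi[planted])
      med_bg <- stats::median(e$mi[!planted])
      if (ph == "tumor") {
        expect_gt(med_planted, med_bg)
        hits <- hits + (med_planted > med_bg)
      } else {
        # module inactive in control: planted pairs look like background
        expect_lt(abs(med_planted - med_bg), 0.15)
      }
    }
  }
  expect_identical(hits, 5L)
})

test_that("write_cohort emits the three standard inputs plus truth JSON", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(tiny_config(seed = 5L))
  write_cohort(co, dir)
  expect_identical(read_expression(file.path(dir, "expression.tsv")), co$counts)
  expect_identical(read_annotation(file.path(dir, "annotation.tsv")), co$annotation)
  lab <- read_labels(file.path(dir, "labels.tsv"), "control")
  expect_identical(lab$phenotype, co$labels$phenotype)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_named(truth, c("modules", "pairs", "progressive", "phenotypes"))
})
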