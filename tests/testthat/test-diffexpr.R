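# Differential expression, signature correlation, progressive genes.

mk_labels <- function(n_ctl, n_tum, extra = NULL) {
  x <- c(stats::setNames(rep("control", n_ctl), sprintf("c%02d", seq_len(n_ctl))),
         stats::setNames(rep("tumor", n_tum), sprintf("t%02d", seq_len(n_tum))))
  if (!is.null(extra)) x <- c(x, extra)
  stage_labels(x, control = "control")
}

test_that("a 4x shift with zero within-group variance gives lfc exactly 2", {
  lab <- mk_labels(3, 3)
  m <- mk_matrix(rbind(rep(c(3, 5), each = 3), rep(4, 6)),
                 samples = lab$sample_id)
  de <- differential_expression(m, lab, "tumor")
  expect_equal(de$lfc[de$gene == "g01"], 2.0)
  # identical group means: lfc 0, ns
  expect_equal(de$lfc[de$gene == "g02"], 0)
  expect_equal(de$status[de$gene == "g02"], "ns")
})

test_that("status thresholds implement the over/under/ns contract", {
  set.seed(9)
  lab <- mk_labels(10, 10)
  base <- matrix(stats::rnorm(200, 8, 0.2), 10, 20)
  base[1, lab$phenotype == "tumor"] <- base[1, lab$phenotype == "tumor"] + 3
  base[2, lab$phenotype == "tumor"] <- base[2, lab$phenotype == "tumor"] - 3
  base[3, lab$phenotype == "tumor"] <- base[3, lab$phenotype == "tumor"] + 1
  m <- mk_matrix(base, samples = lab$sample_id)
  de <- differential_expression(m, lab, "tumor", lfc_threshold = 2, alpha = 0.05)
  expect_equal(de$status[1:3], c("over", "under", "ns"))
  expect_true(all(de$status == ifelse(de$lfc > 2 & de$fdr < 0.05, "over",
                              ifelse(de$lfc < -2 & de$fdr < 0.05, "under", "ns"))))
  expect_error(differential_expression(m, lab, "nope"), "nope")
})

test_that("reversing a contrast flips every log fold change", {
  set.seed(11)
  n <- 8
  x <- c(stats::setNames(rep("a", n), sprintf("a%02d", 1:n)),
         stats::setNames(rep("b", n), sprintf("b%02d", 1:n)))
  m <- mk_matrix(matrix(stats::rnorm(20 * 2 * n, 6), 20), samples = names(x))
  de_ab <- differential_expression(m, stage_labels(x, "a"), "b")
  de_ba <- differential_expression(m, stage_labels(x, "b"), "a")
  expect_equal(de_ab$lfc, -de_ba$lfc)
  expect_equal(de_ab$p_value, de_ba$p_value, tolerance = 1e-12)
})

test_that("BH adjustment matches the closed-form oracle", {
  # worked example: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:25) {
    p <- stats::runif(sample(2:10, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), oracle_bh(p),
                 tolerance = 1e-12)
  }
})

test_that("multi-group contrasts cover all unordered phenotype pairs", {
  set.seed(5)
  x <- unlist(lapply(c("control", "p1", "p2", "p3", "p4"), function(p)
    stats::setNames(rep(p, 4), sprintf("%s_%d", p, 1:4))))
  m <- mk_matrix(matrix(stats::rnorm(10 * 20, 6), 10), samples = names(x))
  res <- multi_group_contrasts(m, stage_labels(x, "control"))
  expect_length(res, choose(5, 2))
  expect_true("p4_vs_p3" %in% names(res))
  two <- multi_group_contrasts(m[, 1:8], stage_labels(x[1:8], "control"))
  expect_length(two, 1)
})

test_that("rank correlation reproduces hand-computed Spearman values", {
  a <- mk_de_result(letters[1:4], c(1, 2, 3, 4))
  b <- mk_de_result(letters[1:4], c(1, 3, 2, 4))
  expect_equal(rank_correlation(a, b), 0.8, tolerance = 1e-12)
  expect_equal(rank_correlation(a, b), oracle_spearman(a$lfc, b$lfc),
               tolerance = 1e-12)
  expect_equal(rank_correlation(a, a), 1.0)
  rev <- mk_de_result(letters[1:3], c(3, 2, 1))
  expect_equal(rank_correlation(mk_de_result(letters[1:3], 1:3), rev), -1.0)
  expect_error(rank_correlation(a, mk_de_result(c("x", "y", "z"), 1:3)),
               "shared genes")
})

test_that("progressive genes need both monotone means and significant steps", {
  set.seed(21)
  phen <- c("control", "s1", "s2", "s3")
  x <- unlist(lapply(phen, function(p)
    stats::setNames(rep(p, 20), sprintf("%s_%02d", p, 1:20))))
  lab <- stage_labels(x, "control")
  idx <- stats::setNames(seq_along(phen) - 1, phen)[lab$phenotype]
  m <- rbind(
    up = 5 + idx + stats::rnorm(80, 0, 0.3),
    flat = stats::rnorm(80, 5, 0.3),
    const = rep(5, 80),
    # monotone in means but one step is far too small to be significant
    weak = 5 + c(0, 1, 1.001, 2)[idx + 1] + stats::rnorm(80, 0, 0.3))
  m <- mk_matrix(m, genes = rownames(m), samples = lab$sample_id)
  pg <- progressive_genes(m, lab, phen)
  expect_equal(pg$gene, "up")
  expect_equal(pg$direction, "up")
  down <- mk_matrix(rbind(dn = 5 - idx + stats::rnorm(80, 0, 0.3)),
                    genes = "dn", samples = lab$sample_id)
  expect_equal(progressive_genes(down, lab, phen)$direction, "down")
  expect_error(progressive_genes(m, lab, phen[1:2]), "at least 3")
})

test_that("tumor signatures correlate above a permuted-label null on shared structure", {
  # two tumor stages share planted DE structure; permuting labels destroys it
  phen <- c("control", "s1", "s2")
  set.seed(31)
  x <- unlist(lapply(phen, function(p)
    stats::setNames(rep(p, 15), sprintf("%s_%02d", p, 1:15))))
  lab <- stage_labels(x, "control")
  m <- matrix(stats::rnorm(40 * 45, 8, 0.5), 40, 45)
  tum <- lab$phenotype != "control"
  m[1:10, tum] <- m[1:10, tum] + 3   # shared signature
  m <- mk_matrix(m, samples = lab$sample_id)
  de1 <- differential_expression(m, lab, "s1")
  de2 <- differential_expression(m, lab, "s2")
  obs <- rank_correlation(de1, de2)
  perm <- replicate(5, {
    shuf <- stage_labels(stats::setNames(sample(lab$phenotype), lab$sample_id),
                         "control")
    rank_correlation(differential_expression(m, shuf, "s1"),
                     differential_expression(m, shuf, "s2"))
  })
  expect_gt(obs, max(perm))
})
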