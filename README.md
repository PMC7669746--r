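# stagenet

Stage-wise gene co-expression network analysis for bulk RNA-seq cohorts
ordered by disease progression (a control group plus consecutive tumor
stages). The package is aimed at computational biologists who want to ask,
on their own staged cohorts, the question that motivates it: *does the
co-expression program change across stages even when the expression program
does not?*

Two complementary layers are computed per phenotype and then compared:

* **Expression.** TMM-normalized log2-CPM; per-stage differential
  expression vs control (log2 fold change `LFC`, Welch test,
  Benjamini–Hochberg FDR; `|LFC| > 2`, FDR < 0.05 by default); Spearman
  rank correlation between stage signatures; and *progressive genes* —
  genes whose group means are strictly monotone across the stage order
  with every consecutive-stage Wilcoxon rank-sum test significant after
  BH.
* **Co-expression.** Per-phenotype mutual-information networks
  (equal-frequency binning into `B = floor(sqrt(n))` bins, plug-in
  estimator `I(X;Y) = Σ p(x,y) log2 p(x,y)/(p(x)p(y))` in bits, optional
  Miller–Madow correction and data-processing-inequality pruning), ranked
  top-*N* sparsification over several orders of magnitude, classification
  of every edge as *cis* (both genes on one chromosome) or *trans*,
  per-chromosome cis rates (cis edges / chromosome genes in network) and
  the global cis fraction `n_cis/(n_cis+n_trans)`, degree distributions
  with `p(k) = a·k^b` fits, multi-network edge intersections (shared-by-all
  and cancer-only sub-networks, Venn regions, divergence
  `1 − |A∩B|/|A|`), and Infomap communities scored by upper-tail
  hypergeometric over-representation with BH FDR.

A synthetic cohort generator plants known co-expression modules (with
chromosomal constraints), monotone progressive genes and negative-binomial
count noise, so the entire chain is validated against ground truth. See the
methods vignette (`vignettes/stagewise-coexpression.Rmd`) for the model,
parameter choices and limitations.

## Worked example

Generate a cohort in which control co-expression is trans-rich (planted
cis fraction 0.200) while tumor stages are cis-rich (0.795), then recover
that wiring from the counts alone:

```r
library(stagenet)

co   <- generate_cohort(cis_cohort_config(seed = 1))
norm <- normalize_counts(co$counts)   # mean>10 filter, TMM, log2-CPM

ctl <- co$labels$sample_id[co$labels$phenotype == "control"]
tum <- co$labels$sample_id[co$labels$phenotype == "stage_i"]
net_ctl <- top_n(mi_matrix(norm$normalized, ctl), 1000)
net_tum <- top_n(mi_matrix(norm$normalized, tum), 1000)
net_tum
#> MI-ranked edge list: 1000 edges, 89 genes
#>    gene_a gene_b       mi
#> 1   g0033  g0041 1.646370
#> 2   g0037  g0053 1.608356
#> 3   g0035  g0041 1.578039
#> ...

s_ctl <- cis_trans_summary(classify_edges(net_ctl, co$annotation))
s_tum <- cis_trans_summary(classify_edges(net_tum, co$annotation))
sprintf("control cis fraction: %.3f (planted %.3f)",
        s_ctl$cis_fraction, expected_cis_fraction(co$truth, "control"))
#> "control cis fraction: 0.212 (planted 0.200)"
sprintf("stage_i cis fraction: %.3f (planted %.3f)",
        s_tum$cis_fraction, expected_cis_fraction(co$truth, "stage_i"))
#> "stage_i cis fraction: 0.785 (planted 0.795)"

pairwise_divergence(net_ctl, net_tum)
#> 0.999
```

The recovered cis fractions match the planted wiring, and the two top-1000
networks share almost nothing (divergence 0.999) — the co-expression
programs differ radically even though both phenotypes were simulated from
the same gene panel. Degree-distribution fitting is exercised on generated
power-law data:

```r
set.seed(42)
k <- 1:30
p <- 2941.8 * k^-1.842 * exp(rnorm(30, 0, 0.01))
fit_power_law(data.frame(k = k, p = p))
#> power law y = a*k^b: a = 2981, b = -1.857 (correlation 1.000, R-square 1.000)
```

The full pipeline (simulate → normalize → DE/progressive → MI networks →
topology per cut-off → intersections → communities/enrichment → manifest)
runs from one call and is reproducible seed-for-seed:

```r
run_pipeline(
  pipeline_config(synthetic = demo_config(1), cutoffs = c(50L, 100L, 300L, 1000L), seed = 1L),
  "demo_run")
```

A thin command-line wrapper lives at `inst/scripts/stagenet.R`
(`Rscript stagenet.R run --demo --seed 1 --out demo_run`).

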