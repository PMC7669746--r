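---
title: "Methods: stage-wise co-expression network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-wise co-expression network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stagenet)
```

# Scope and rationale

`stagenet` analyses how bulk RNA-seq expression *and* co-expression change
across an ordered series of phenotypes — a control group followed by
consecutive tumor progression stages. The two views are deliberately kept
side by side because they can disagree: differential-expression signatures
may be nearly identical between stages while the co-expression networks
built from the same samples share almost no edges. The package provides the
full chain needed to quantify that contrast: normalization, per-stage
differential expression, detection of genes that change monotonically with
stage, per-phenotype mutual-information (MI) networks, separation of edges
into intra-chromosome (*cis-*) and inter-chromosome (*trans-*) contacts,
multi-network intersection across a sweep of network sizes, and
community-wise over-representation.

All of it is exercised against a synthetic cohort generator that plants
known structure, so every downstream claim has a ground truth to be checked
against.

# Normalization

Raw counts are filtered by mean expression (`filter_by_mean()`, strict
`mean > 10` by default: a gene whose mean is exactly at the threshold is
dropped). Filtering happens on raw counts, before normalization — the
threshold is a count scale, and filtering first keeps the TMM fit away from
the all-zero tail.

Between-sample normalization is trimmed-mean-of-M-values
(`tmm_factors()`), computed by edgeR's implementation with the canonical
trim fractions (30% on M, 5% on A) and precision weights; the reference
sample is chosen by the upper-quartile rule and factors are rescaled to a
geometric mean of 1. Note the two common conventions — "reference factor
is 1" and "geometric mean is 1" — are mutually exclusive; the package uses
the geometric-mean convention of count-based DE tools. `log_cpm()` then
maps counts to `log2((count + prior) / (lib_size * factor) * 1e6)`, finite
at zero and strictly monotone in the count.

Within-lane corrections (GC content, gene length) and batch correction are
intentionally out of scope: they require covariates and batch structure the
pipeline's inputs do not carry, and a pre-corrected matrix can be supplied
transparently.

# Differential expression and progressive genes

Per-stage contrasts against control (`differential_expression()`) report
the difference of group means on the log2 scale (LFC), a two-sided Welch
t-test p-value, and Benjamini–Hochberg FDR across genes. A gene is called
`over` when `lfc > 2` and `fdr < 0.05`, `under` symmetrically; the
between-stage contrasts (`multi_group_contrasts()`) relax the LFC cut-off
to 0.5, since consecutive stages differ far less than tumor vs control.
The Welch test was chosen over count-model machinery (empirical-Bayes
moderation, likelihood-ratio tests on GLMs) to keep the statistic simple
and pluggable on the log scale; with dozens of samples per group the
moderation matters little, and the contract (LFC + BH + status) is
independent of the test used.

Signature similarity between stages is summarized by Spearman correlation
of the LFC vectors (`rank_correlation()`) over all genes passing the mean
filter — not only significant ones — so the statistic does not depend on a
significance threshold.

`progressive_genes()` returns genes whose per-stage means are strictly
monotone over the full phenotype order *and* whose every consecutive-stage
comparison is significant after BH adjustment across all genes ×
consecutive pairs. The consecutive tests are two-sided Wilcoxon rank-sum
tests: stage groups are disjoint patient sets, so the paired (signed-rank)
variant is not applicable; this is a deliberate reading of "Wilcoxon
between stages" for unpaired designs. Monotonicity is required on means
(not medians) so the criterion is exactly the quantity the generator
plants.

# Mutual-information networks

`mutual_information()` discretizes each expression profile by
equal-frequency binning into `B = floor(sqrt(n))` bins and evaluates the
plug-in estimate `sum p(i,j) log2(p(i,j)/(p(i) p(j)))` on the joint table;
`mi_matrix()` computes all pairs at once via per-bin indicator
cross-products (a handful of dense matrix products), and is identical,
pair for pair, to the scalar route. Design points worth knowing:

* **Determinism.** Within-vector ties are broken by original index during
  binning and edge ranking breaks MI ties lexicographically, so networks
  and top-N cut-offs are reproducible without any seed.
* **Rank invariance.** Equal-frequency binning makes MI exactly invariant
  under strictly increasing transforms of either profile; the log2-CPM
  scale is a convenience, not an assumption.
* **Chance floor.** The plug-in estimator is biased upward by roughly
  `(B-1)^2 / (2 n ln 2)` bits under independence (≈ 0.43 bits at `n = 60`,
  `B = 7`); with `B = floor(sqrt(n))` the joint table has about as many
  cells as samples, so the floor is substantial and higher-order terms add
  some 10–20%. Edge *ranking* is unaffected (the bias is common to all
  pairs), which is why the pipeline thresholds by rank (top-N), never by
  an absolute MI value. A Miller–Madow correction
  (`mi_config(estimator = "miller_madow")`) is available and shrinks the
  floor, but the default stays with the plain plug-in for transparency.
* **Constant profiles** carry no information and return 0 with a warning.

`dpi_prune()` applies the data-processing-inequality step familiar from
MI-network tools: in every gene triangle the weakest edge is marked when
strictly below `(1 - tolerance)` times the smaller of the other two, and
all marked edges are removed simultaneously after the scan. It is **off by
default** in the pipeline: the analysis ranks raw MI edges across cut-offs,
and pruning would entangle the cut-off sweep with triangle topology.

`top_n()` takes ranked prefixes, so cut-offs are nested
(`top_n(e, 100)` is a prefix of `top_n(e, 1000)`) — the property that makes
proportions comparable across the sweep.

# cis/trans topology

`classify_edges()` flags an edge *cis* when both genes carry the same
chromosome label (an optional `chr` prefix is stripped and case is folded,
so UCSC and GENCODE dialects compare equal). Two summary conventions exist
for "cis rate" and they disagree: dividing by the network's total edges
bounds the quantity by 1, while dividing a chromosome's cis edges by that
chromosome's genes in the network can exceed 1 on densely wired
chromosomes. The package computes **both**, under distinct names:
`cis_fraction` (global, `n_cis / (n_cis + n_trans)`) and the per-chromosome
`cis_rate` (cis edges / genes in network). The per-gene denominator is the
convention adopted for per-chromosome reporting precisely because observed
values straddling 1 are meaningful under it.

Degree distributions (`degree_distribution()`) cover all nodes appearing in
the edge list — an edge-defined network has no degree-zero nodes — and
`fit_power_law()` fits `p(k) = a k^b` by nonlinear least squares **on the
linear scale**, initialized from the log–log OLS solution. When the log–log
solution already interpolates the points (noiseless data), it is returned
directly: refining a zero-residual start is numerically ill-posed. The fit
accepts either normalized probabilities or raw counts as `p`, since both
conventions appear in practice; `correlation` (Pearson, fitted vs observed)
and `r_square` are reported alongside `a` and `b`.

# Intersections across cut-offs

`intersect_networks()` does exact set algebra on canonical unordered gene
pairs: edges shared by all phenotypes, phenotype-specific edges, pairwise
counts, full Venn regions, and — when a control is designated — the
"cancer-only" set present in every tumor network and absent from control.
Networks are always compared at matched top-N sizes (not matched MI
thresholds): equal sizes make shared proportions comparable, and MI values
play no role in membership. `intersection_curve()` repeats the algebra at
each cut-off and reports `|shared| / n`, the quantity whose decay with
network size is the multi-scale signature of phenotype-specific wiring.

# Communities and over-representation

`detect_communities()` runs Infomap (default, 10 trials, two-level) or
label propagation on the MI weights, with a mandatory seed since both
algorithms are stochastic. Whatever the algorithm returns, communities are
split along connected components — a community can never span two
components — and ids are renumbered deterministically. `enrich()` scores
each community of at least 5 genes against each gene set with the
upper-tail hypergeometric probability `P(X >= k)`, BH-adjusted across all
(community, set) pairs. BH is used rather than any tool-specific
multiple-testing scheme; the enrichment universe is the set of genes
surviving the mean filter — the measured background — not the whole
annotation.

# The synthetic cohort generator

`generate_cohort()` draws negative-binomial counts
(`var = mu + phi mu^2`, dispersion `phi = 0.1` by default — a typical bulk
tissue value) around per-gene baselines drawn log-uniformly from 50–500.
Three kinds of structure can be planted:

* **Co-expression modules** (`module_spec()`): genes sharing a latent
  factor in the phenotypes where the module is active. The total log2 SD
  of a module gene is fixed at 1.5 — the dynamic range of a strongly
  co-regulated module — and `latent_strength` is the fraction of that
  variance carried by the shared factor. Two design points matter:
  * *Sign-alternating loadings.* Half the module loads positively, half
    negatively on the factor. A module is therefore composition-neutral:
    its total count barely moves with the factor, mimicking the fact that
    any real module is a vanishing fraction of the transcriptome, so
    library-size normalization stays unbiased even when planted modules
    cover most of a small simulated gene panel. MI is blind to correlation
    sign, so the planted wiring is unchanged.
  * *Identifiability.* For recovery benchmarks the planted-pair MI must
    clear the plug-in chance floor described above (≈ 0.43 bits plus an
    extreme-value tail to ≈ 0.75 bits over ~19k null pairs at `n = 60`).
    With SD 1.5 and `latent_strength = 0.95` the planted correlation after
    count noise is ≈ 0.87, i.e. ≈ 1.4 bits — cleanly above the floor. At
    `latent_strength = 0.6` planted pairs still separate from background
    in the median, but not pair-by-pair; the bundled cohort designs choose
    strengths accordingly.
* **Chromosomal wiring**: genes are assigned to chromosomes round-robin
  (balanced per-chromosome counts for cis-rate statistics) unless a module
  is `cis_constrained`, which forces all its genes onto one chromosome so
  every planted pair is cis. A module of up to 22 consecutive gene indices
  left unconstrained lands on 22 distinct chromosomes — all pairs trans.
* **Progressive genes** (`progressive_spec()`): the expected count is
  multiplied (or divided) by `fold_step` at each consecutive phenotype, so
  the monotone ground truth is exact on the mean scale.

The generator is a pure function of its config: one seed, one RNG stream,
fixed iteration order — identical seeds give byte-identical cohorts.

What the generator does **not** emulate: batch effects, GC/length bias,
library-size confounding beyond what sampling induces, isoforms, and the
heavy-tailed mean–variance relationships of real cohorts. Passing
recovery tests therefore demonstrates that the estimators and set algebra
do what they claim under NB noise with planted truth — not that any
particular biological dataset will behave as cleanly.

## Bundled study designs

Four canned configs fix the conditions used by the tests and the
acceptance script (all five phenotypes, 22 chromosomes, dispersion 0.1):

* `cis_cohort_config()` — control trans-rich (planted cis fraction 0.200)
  vs tumor cis-rich (0.794; the closest disjoint-module design fitting 200
  genes), 60 samples per phenotype. Used for cis/trans recovery and for
  the control-trans-excess property across cut-offs
  {100, 300, 1000, 3000}.
* `intersection_cohort_config()` — ten small modules shared by all
  phenotypes with latent strengths graded 0.95 → 0.60 (so the global MI
  ranking of shared pairs is roughly consistent across networks), plus
  weaker tumor-only and control-only modules. Yields the falling
  shared-proportion curve across cut-offs {100, …, 10000}.
* `progressive_cohort_config()` — four progressive genes (two up, two
  down, fold step 2) over five phenotypes, 60 samples each, on a pure NB
  background.
* `demo_config()` — everything at once at 40 samples per phenotype; the
  end-to-end pipeline demo and determinism check.

These sizes (200 genes, 40–60 samples per phenotype, cut-offs up to
10,000) keep a full test run within a couple of minutes on one core while
leaving every planted effect comfortably detectable; they are the
package's chosen problem sizes for its own validation.

# Degenerate inputs and numerical conventions

* Zero within-group variance in a DE contrast: the t-statistic is
  undefined; the contrast is decided by the mean difference alone (p = 1
  if equal, 0 otherwise).
* Wilcoxon comparisons between identical constant groups return p = 1.
* An empty mean-filter result warns rather than errors (downstream code
  gives located errors of its own).
* `largest_component()` breaks size ties toward the component containing
  the lexicographically smallest node; all string ordering uses C-locale
  radix sorting, so results do not depend on the session locale.
* Edge lists are canonical: `gene_a < gene_b`, MI descending, ties broken
  by pair order; readers re-canonicalize on input and reject duplicates,
  self-loops and negative MI with located messages.

# Known limitations

* The Welch-on-log2 DE is a simplification; strongly dispersed low-count
  genes are better served by count models. The test statistic is isolated
  in one internal function precisely so a moderated variant can be
  plugged in.
* The MI estimator is the plain binned plug-in; kernel or adaptive
  estimators would have lower bias at small n, at the price of
  determinism and simplicity.
* Per-chromosome cis rates can exceed 1 and are not comparable across
  chromosomes with very different gene counts in the network.
* Infomap on weighted graphs can return different partitions across seeds
  on near-degenerate structures; determinism is guaranteed only per
  (method, seed).
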