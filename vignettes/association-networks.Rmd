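---
title: "Inferring microbial association networks with assocnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microbial association networks with assocnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocnet)
```

## The problem

Marker-gene surveys (16S rDNA and relatives) measure the abundance of many
microbial taxa across many samples. Pairs of taxa whose abundance profiles
track each other (co-presence) or avoid each other (mutual exclusion) are
candidates for ecological relationships — or at least for shared responses
to environmental drivers. Two statistical features of sequencing data make
naive correlation networks unreliable:

* **Sequencing depth varies per sample**, so counts must be normalized
  (divided by the column sum) or rarefied. Normalization closes each sample
  to unit sum: the data become *compositional*, and compositions induce
  spurious negative correlation between taxa even when the underlying
  abundances are independent.
* **Any single association measure has characteristic failure modes** —
  correlations are sensitive to compositional bias and matching zeros,
  Bray-Curtis to outliers, mutual information to small sample sizes.

`assocnet` addresses both: an *ensemble* of measures is combined by voting
and by dependent p-value merging, and edge significance is assessed against
a *renormalized* permutation null that carries the same compositional bias
as the observed scores.

## Pipeline

The run is organized as preprocessing, initial network computation, and
assessment of significance; `assocnet()` is the single driver.

### Preprocessing

* `filter_min_occurrence(table, row_minocc, keep_sum)` removes taxa with
  fewer than `row_minocc` non-zero observations (rare taxa carry almost no
  pairwise information and inflate the multiple-testing burden). With
  `keep_sum` the removed rows' column sums are retained as a
  `filtered_sum` pseudo-row: it never enters edge inference but stays in
  the compositional denominator during normalization and null
  renormalization.
* `normalize_columns()` divides each entry by its column sum (relative
  abundances); `rarefy_columns()` instead subsamples each sample without
  replacement to a common depth.
* `aggregate_higher_taxa()` appends, for every rank from kingdom to genus,
  a row per taxon name equal to the column sums of its member OTUs, so
  links between higher-level taxa (say an order and a genus from a
  different lineage) can be inferred. Aggregation stops at genus: the OTU
  rows themselves stand in for species-level resolution. Aggregates are
  grouped by taxon *name*; identically named taxa under different parents
  are merged, a simplification acceptable for rank-prefixed lineages.
* `eligible_pairs()` applies the pair constraints: the object-group mode
  (`between_groups_only` yields bipartite networks, e.g. taxa versus
  metabolites), and *parent-child exclusion*, which drops any pair in which
  one full taxonomic path is a prefix of the other — a parent's counts
  contain its child's, so such edges are trivial. Sample-metadata rows
  (merged in via `merge_feature_rows()`, e.g. pH) always remain eligible to
  pair with taxa and with each other, whatever the group mode, and appear
  as metadata nodes in the final network.
* Missing values are handled per pair: `pairwise_complete()` drops sample
  positions missing in either profile and flags pairs with fewer than 3
  complete positions as unusable (correlation is undefined below that; a
  score over so few points would be noise anyway).

### Measures

`compute_measure()` implements: Pearson, Spearman, Kendall tau-b
(tie-corrected — count data are tie-heavy), Bray-Curtis
$\sum_i |x_i-y_i| / \sum_i (x_i+y_i)$, Steinhaus ($1-$Bray-Curtis),
symmetrized Kullback-Leibler on pseudocounted renormalized probability
vectors, Euclidean distance, and for presence/absence data the Jaccard
distance and the hypergeometric upper-tail probability of the observed
co-presence count given the two marginals. Numeric input is auto-binarized
at $>0$ for the incidence measures.

Two estimator choices were genuinely open and are fixed as follows:

* **Mutual information** uses equal-frequency discretization into
  $\lceil\sqrt{n}\rceil$ bins with the plug-in (maximum-likelihood)
  entropy estimate, reported in nats. MI estimation is a debated topic; a
  simple, documented estimator is preferred here over an unstated one. MI
  is a general dependency measure: it carries no sign, and its edges are
  colored only by agreeing signed measures at merge time.
* **KL pseudocount**: the smallest non-zero value of the pair (fallback
  $10^{-6}$ for degenerate pairs) is added before renormalizing, the
  minimal intervention that avoids infinite terms at zeros without
  swamping small real counts.

Floating-point note: all measures are mathematically symmetric, but
summation order is not associative in floating point; `compute_measure()`
canonicalizes the argument order so that symmetry holds *exactly*.

### Thresholds

`select_edges()` converts scores to signed candidates. Manual thresholds
use fixed cutoffs; automatic mode keeps the `edge_number` top- and/or
bottom-scoring pairs per measure (the cutoff is the k-th order statistic).
For similarity measures the top tail is co-presence; for dissimilarities
the mapping reverses (small distance = co-presence). Ties at the cutoff are
broken by lexicographic pair id so the candidate count is exact and
deterministic. For unsigned measures `top_and_bottom` degrades to `top`
with a notice — a "bottom" MI tail has no meaning. In the rare case where
`2 * edge_number` exceeds the pair count and one pair qualifies for both
tails, it is dropped from both (a pair cannot credibly be co-present and
mutually exclusive at once).

### Significance

* **Permutation null** (`permutation_distribution`): both rows of a pair
  are independently permuted across samples. With `renormalize`, the
  permuted pair is swapped into the full matrix (including `filtered_sum`)
  and every column re-closed to unit sum before scoring. Renormalization is
  applied against the *full* matrix rather than the pair alone, because the
  compositional constraint acts through the whole community's denominator.
  The two permutations of an iteration are shared across measures so the
  per-measure null scores stay coupled, like the observed scores.
* **Bootstrap** (`bootstrap_distribution`): per iteration one
  sample-with-replacement column draw is shared across *all* pairs. Sharing
  the draw preserves cross-edge and cross-measure dependence, which the
  Brown covariance estimate (below) needs.
* **P-value**: `reboot_pvalue()` fits a normal to the permutation null
  $(\mu_0, \sigma_0)$ and tests the bootstrap mean:
  $p = 2\,\Phi(-|\mu_b-\mu_0|/\sigma_0)$, clamped to $(10^{-300}, 1]$. The
  statistic is a distance between two fitted distributions, so ~100
  iterations already give stable p-values where a raw empirical tail count
  would be quantized at $1/(\text{iterations}+1)$. An alternative scaling
  by the bootstrap standard deviation is available via `method =
  "boot_sd"`. The empirical add-one tail (`permutation_pvalue()`, with
  sign-appropriate tails) is kept for permutation-only runs. An optional
  `stability_filter()` additionally discards edges whose null mean falls
  inside the central bootstrap interval.
* **Merging**: `merge_pvalues()` implements Fisher's
  $X = -2\sum \ln p_i \sim \chi^2_{2k}$ and Brown's dependence-corrected
  version: $X$ is referred to $c\,\chi^2_f$ with $E = 2k$,
  $\mathrm{Var} = 4k + 2\sum_{i<j}\mathrm{cov}_{ij}$, $f = 2E^2/\mathrm{Var}$,
  $c = \mathrm{Var}/(2E)$. The covariances come from Brown's cubic
  polynomial approximation (separate fits for $r \ge 0$ and $r < 0$)
  applied to $r_{ij}$, the product-moment correlation between measures
  $i$ and $j$'s observed score vectors across the initial network's edges,
  after orienting every measure in the similarity direction (dissimilarity
  scores negated). With $r = 0$ Brown reduces exactly to Fisher; with
  perfectly redundant measures it returns the single-measure p-value
  rather than double-counting evidence.
* **Correction**: `correct_multiple_testing()` (BH step-up or Bonferroni)
  over the initial network's edges only — those are the hypotheses actually
  tested.

### Merging and voting

`merge_edges()` keeps a pair when at least `minsupport` measures proposed
it (`intersection` = all of them). Sign semantics: unsigned contributors
(MI) are neutral and inherit the signed consensus; if signed contributors
disagree, the edge is discarded outright — an association that one measure
calls co-presence and another calls exclusion is not trustworthy at any
support level. When the significance stage ran, voting applies to the
significance-surviving candidates (preprocess → initial network →
assessment → final network); `pmerge` is the weighted-voting complement of
`minsupport` and the two compose freely. Without p-value merging
(`pmerge = "none"`), an edge's p is the smallest of its per-measure
p-values. The merged edge weight is the corrected q-value when available,
else the mean similarity-oriented score. `build_multigraph()` skips merging
and returns one edge per supporting measure.

### Output

`annotate_nodes()` attaches degree (total / positive / negative /
unsigned), row sum, prevalence, node type and one attribute per lineage
rank. `write_network()` emits GML (all attributes, numbers at 17
significant digits so a round trip is faithful), GraphViz dot
(green/red/grey edges), or a flat edge TSV; nodes and edges are written in
lexicographic order for reproducible diffs. `read_adjacency_matrix()` and
`read_network_gml()` import networks.

## The two-launch protocol

Resampling dominates run time, so the pipeline separates it from network
generation. Launch one (`resample=shuffle_rows`, `renormalize=true`,
`save_null=F`) computes and saves permutation distributions and an
intermediate network. Launch two (`resample=bootstrap`, `load_null=F`,
`pmerge=brown`, `multitest=benjaminihochberg`) computes bootstrap
distributions and the final network. Stores are written with 17
significant digits, so reloading reproduces scores bit-for-bit and the
two-launch result is *identical* to a single-process run with the same
seed — a property the test suite asserts on the serialized edge table.
With both stores loaded (`quick_regenerate()`), thresholds, merging and
filters (e.g. `positive_only`) can be re-run in seconds without any
resampling. All randomness derives from one user seed through fixed
per-stage offsets.

## The synthetic-community generator

`simulate_community()` produces test tables with known structure:

* latent per-taxon log-normal abundances (log-scale spread sd 1.5,
  matching the orders-of-magnitude abundance range of real OTU tables);
* planted pairs share a latent sample factor with loadings
  $\pm\sqrt{\rho}$, giving latent log-abundance correlation $\pm\rho$
  (default 0.9, a strong association); partners also share their
  characteristic abundance, so the planted signal is expressed in profile
  similarity (Bray-Curtis) as well as in rank correlation — without this a
  dissimilarity measure could not in principle see the planted
  co-presence, and an ensemble benchmark would be testing the generator,
  not the method;
* each sample draws a sequencing depth uniformly from 5,000–20,000 and its
  counts from a multinomial over the latent relative abundances. The
  multinomial closure (rather than independent Poisson draws) means the
  compositional bias the renormalized null targets is actually present in
  test data;
* optional zero-inflation and a random nested taxonomy for
  parent-child-exclusion tests.

What it does **not** emulate: phylogenetic correlation among related taxa,
time-series autocorrelation, batch effects, chimeras or other artifacts,
and indirect multi-taxon interaction chains. Passing the recovery benchmark
therefore shows the pipeline recovers planted pairwise structure under
compositional closure and depth variation — not that it resolves direct
from indirect associations in real communities (no correlation-based
method does).

`recovery_benchmark()` runs the reference validation: 100 taxa × 100
samples, 20 positive + 20 negative planted pairs at effect 0.9, spearman +
bray_curtis, automatic top-and-bottom thresholds at 250 edges per side,
renormalized permutation and bootstrap at 100 iterations each, Brown + BH
at q ≤ 0.05, minsupport 2. Evaluation: AUROC of the merged p-value ranking
over initial-network pairs against the planted labels, and sign accuracy on
recovered planted edges. These sizes run in well under a minute of scoring
plus a few minutes of resampling on one core; iteration counts beyond ~100
change the parametric p-values little, which is why the default stays
at 100.

## Numerical choices and degenerate inputs

* Automatic thresholds, exports, and pair enumeration sort
  lexicographically; every tie-break is deterministic.
* Constant vectors make correlations unusable (`NA`) rather than erroring;
  unusable scores are recorded and never become candidates.
* A degenerate (zero-spread) permutation null yields p = 1 with a warning
  instead of a division by zero.
* Zero-sum columns are an error in `normalize_columns()` (the sample
  carries no information and the closure is undefined).
* Probabilities are clamped to $(10^{-300}, 1]$; q ≥ p is guaranteed by
  the correction methods.
* The 3-complete-samples minimum for scoring is enforced at the pair level
  (`pairwise_complete()`); distance measures themselves evaluate at any
  length, which keeps closed-form anchors like the 2-point Euclidean
  distance available.

## Known limitations

* Edges are associations, not interactions: environmental drivers and
  compositional coupling create real but indirect associations
  (precision against *planted* truth is accordingly modest even when
  ranking is nearly perfect).
* Brown's polynomial is an approximation fitted for Gaussian scores; with
  heavily tied or very short profiles the covariance estimate is rough.
* HDF5 biom files are only readable where the installed `biomformat`
  stack supports them; the JSON 1.0 dialect is the native path.
* The MI estimator is the simple plug-in form; entropy bias at small n is
  not corrected (unsigned MI edges are therefore best used alongside
  signed measures, as the merge semantics encourage).
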