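---
title: "Methods: condition-specific network perturbation mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condition-specific network perturbation mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pertnet` contrasts a disease condition with its precursor and with control
groups by coupling differential expression with shortest-path mining over a
fold-change-weighted interaction network. This vignette documents the
models, the defaults and why they were chosen, the numerical conventions,
and what the synthetic benchmark does and does not establish.

## Differential expression model

Counts for gene *g* in sample *j* are modelled as negative binomial with
mean μ and dispersion α under the variance function Var = μ + αμ². In the
`size` convention of `rnbinom()`, α = 1/size; `simulate_counts()` and
`wald_test()` share this parameterization.

The stages of `wald_test(cm, test, reference)`:

* **Normalization** — median-of-ratios size factors (`estimate_size_factors()`):
  for sample *j*, the median over genes with a positive geometric mean of
  count/geomean, rescaled to geometric mean 1. If no gene is expressed in
  every sample the function falls back to total-count ratios and says so.
* **Dispersion** — pooled method of moments (`estimate_dispersion()`): the
  df-weighted within-group variance s² and pooled mean μ̂ give
  α̂ = max((s² − μ̂)/μ̂², 10⁻⁸). The floor keeps the model variance positive
  and absorbs all-zero and underdispersed genes. There is no shrinkage
  across genes, no independent filtering and no outlier handling: the
  downstream network stage consumes only (fold change, p), and the
  benchmark criterion is planted-truth recovery, not equality with any
  particular DE implementation.
* **Wald test** — log₂FC = log₂((m_t + c)/(m_r + c)) with group means m of
  normalized counts and pseudocount c = 0.5 (keeps ratios finite when one
  group is all zero; the value is half the smallest observable count and is
  config-exposed). The delta method gives
  Var(log₂FC) = [Var(m_t)/(m_t + c)² + Var(m_r)/(m_r + c)²]/ln²2 with
  Var(m) = (μ̂ + α̂μ̂²)/n per group; the statistic log₂FC/SE is referred to a
  standard normal, two-sided. With five samples per group this is mildly
  anti-conservative (a t reference with ~8 df would be exact if α were
  known); measured on 2000 null genes the p < 0.05 rate is ≈ 0.08–0.10,
  inside the contracted [0.025, 0.10] band, and the |log₂FC| ≥ 1 fold gate
  keeps the realized null DEG rate far lower (< 1 %).
* **Multi-group data** are subset to the two compared groups before
  normalization and dispersion pooling. Pooling across *all* groups (as a
  joint model with contrasts would) was deliberately not emulated; with the
  shipped group sizes the two-group pooling is simpler and testable, and
  the deviation is confined to `wald_test()`.
* **DEG call** — |log₂FC| ≥ log₂(2) inclusive and p < 0.05 strict, the
  conventional "2-fold change, p < 0.05" rule; a flag switches to the
  Bonferroni-adjusted p. Comparisons against a single-sample group are
  computed (the lone sample's model variance is used) but flagged
  low-confidence.

## Condition networks and TopNets

For each comparison the network is weighted twice:

* node weight N_u = FC_u ("active": upregulated genes weigh high) or
  1/FC_u ("repressed"); fold changes enter on the ratio scale, unthresholded,
  for every gene with an expression value. Genes in the network without
  expression are dropped, not imputed — a fabricated neutral weight would
  create artificial shortcuts; the count of dropped nodes is logged and kept
  in provenance.
* edge weight w_uv = 1/√(N_u·N_v). Raising either endpoint's perturbation
  strictly lowers the edge weight, so minimum-cost paths prefer perturbed
  genes. Scaling all node weights by c scales all costs by 1/c and leaves
  the ranking invariant — path selection depends only on relative
  perturbation.

`shortest_paths_all_pairs()` computes all-vs-all Dijkstra costs and
reconstructs, per reachable ordered pair, the minimum-cost path. Two
conventions make outputs platform-independent and deterministic:

* **Normalization over path length** means cost divided by the *number of
  edges* — the mean edge weight along the path. This makes one-edge and
  long paths comparable; without it, single cheap edges would always
  dominate multi-edge chains through equally perturbed regions.
* **Tie-breaking** among equal-cost shortest paths is by lexicographically
  smallest node sequence (C-locale ordering), applied both in path
  reconstruction and in ranking. Ties are measure-zero for continuous
  fold changes but routine in small test graphs.

Ranked paths are selected either as the top fraction (default 0.5 %, kept
deliberately small so TopNets stay interpretable subnetworks rather than
re-painting the whole graph) or by `permutation_threshold()`: node weights
are permuted k times (k ≥ 10, default 100), edge weights and normalized
costs recomputed, and the α-quantile of the pooled null taken as the
cutoff. The permutation null preserves topology and the weight multiset
while destroying the weight–position association, which is exactly the
signal TopNets claim to find. Both the choice and its parameters are
recorded in TopNet provenance. Edges are treated as directed as loaded
(curated regulatory networks are directed); `undirected = TRUE`
symmetrizes.

The TopNet is the union of nodes/edges of the selected active paths, the
same for repressed, their node intersection as the common part, and the
DEG list intersected with the node union as the captured DEGs.

## Signature extraction

`characteristic_degs()` subtracts from the primary comparison's captured
DEGs every gene captured by any control comparison's TopNet, in one pass
per control set with sizes recorded at each step. Exclusion is by gene
identity, not (gene, direction): a gene whose perturbation also surfaces in
a control contrast is not characteristic of the primary one regardless of
sign; directions are kept for reporting. The operation is monotone
(enlarging a control set can only shrink the signature) and annihilating
(subtracting the primary set itself leaves nothing) — both are tested
properties.

Sample clustering on the signature uses row Z-scores (each gene scaled to
mean 0, sd 1 across samples), Euclidean distance and average linkage.
Metric and linkage are documented defaults, not claims: they are the
conventional heatmap settings and are config-exposed. Constant rows are
dropped with a warning; the linkage contains no randomness, so leaf order
is a pure function of the matrix.

## Enrichment and clinical statistics

Over-representation uses the one-sided Fisher / hypergeometric upper tail
P(X ≥ k) per term, BH-adjusted across terms. The universe defaults to the
genes shared by the expression table and the collection — a reproducible,
audit-able background (web services' internal backgrounds are not). Terms
with p < α (strict, default 0.05) count as significantly perturbed.

Clinical summaries report per-group mean ± SD (n − 1 denominator) with
missing values excluded pairwise; the neutrophil-to-lymphocyte ratio is
computed per patient first and then summarized, so the group NLR carries an
SD. Group comparisons default to Welch's t (no equal-variance assumption);
Mann–Whitney is exposed for small or skewed samples. The comparison test is
a documented default — the descriptive tables this mirrors do not name one.

## The synthetic benchmark

`simulation_config()` defaults describe the study conditions the package
ships and tests at:

| parameter | default | rationale |
|---|---|---|
| groups | ARF 5, RHD 5, CHD 5, HC 2 | the sequenced cohort structure, including the small-n healthy group pathology |
| baseline | log-normal, log-mean log(100), log-sd 1 | typical bulk RNA-seq expression spread |
| dispersion α | 0.1 | realistic whole-blood overdispersion |
| library sizes | log-uniform in [0.7, 1.4] | makes normalization non-trivial; `c(1, 1)` disables |
| network | 300 nodes, preferential attachment, m = 2, directions uniform at random | heavy-tailed degrees resemble curated PPI networks while staying seedable |
| planted module | 20 connected genes, log₂FC = 2 | strong but not trivial effect at n = 5 |

`demo_study()` plants three disjoint connected modules (BFS expansion from
a seeded start): 20 genes up in RHD, 10 up in ARF, 10 up in CHD. Because
planted effects attach to *groups*, a gene perturbed in RHD necessarily
also differs in any RHD-vs-HC contrast — a module visible *only* in
RHD-vs-ARF cannot coexist with RHD-vs-HC as a control (β_RHD ≠ β_ARF
together with β_RHD = β_HC = β_ARF is contradictory). The demo design
therefore uses ARF-vs-HC and CHD-vs-HC as controls, which keeps the ground
truth identifiable: the ARF decoys are captured both in the primary TopNet
(as downregulated) and in the ARF-vs-HC control TopNet, and are excluded;
the RHD module survives. The verbatim four-comparison design (primary
RHD-vs-ARF; controls RHD-vs-HC, ARF-vs-HC, CHD-vs-HC) remains available as
`rhd_study_design()` for real data, where effects are not group-additive.

What passing the benchmark shows: the mechanics — NB moments, weight
formulas, Dijkstra agreement with exhaustive enumeration, exclusion
algebra, determinism — and that the pipeline recovers a strong connected
planted signal at the study's sample sizes. What it does not show:
performance on real data with correlated genes, batch structure,
library-composition effects, or curated networks whose degree distribution
and direction semantics differ from preferential attachment; nor any claim
about the specific genes of any real cohort. The clinical generator draws
each parameter independently per group from normal profiles — it emulates
group-level means and SDs, not within-patient correlation between
parameters.

## Numerical conventions and problem sizes

* Dispersion floor 10⁻⁸; pseudocount 0.5; fold gate inclusive, p strict.
* Path-cost tie tolerance 10⁻⁹·(1 + cost) when testing the optimality
  condition during reconstruction; costs themselves come from igraph's
  Dijkstra untouched.
* All generators are pure functions of (config, seed); the RNG state of the
  caller is saved and restored. Pipeline reruns with one seed are
  byte-identical, which the tests assert file-by-file.
* Test and acceptance problem sizes — 300-node networks, 400-gene matrices,
  2000-gene null calibration, 500 power replicates, 100 oracle graphs of
  ≤ 10 nodes, the full hypergeometric battery N ≤ 60 — were chosen so the
  whole suite exercises every contract in about two minutes on one core
  while keeping Monte-Carlo error well inside the asserted bounds.

## Known limitations

* The Wald test's normal reference is anti-conservative at n = 5; the
  contract band [0.025, 0.10] on the null p < 0.05 rate makes this
  explicit rather than hiding it.
* Single-sample groups (HC, n = 2 cohorts splitting further) yield
  low-confidence flags, not errors; their SEs rest on one sample's model
  variance.
* The permutation threshold pools all pairs' normalized costs; at its
  default k = 100 on large networks it is the slow path and is therefore
  not the default selector.
* Exclusion by gene identity means a gene flipping direction between
  comparisons is still excluded; pairwise direction-concordant overlaps are
  available separately via `common_degs()`.
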