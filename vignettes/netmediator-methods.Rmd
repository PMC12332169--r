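---
title: "netmediator: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netmediator: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmediator)
```

## The problem

Differential expression ranks genes by how much their *own* transcript
level separates two groups. Many genes that organise a transcriptomic
shift — signalling hubs, transcription factors under post-transcriptional
control — barely move themselves, and are invisible to that ranking.
`netmediator` implements a sample-specific network strategy for two-group
cohorts (the motivating setting is HPV-positive versus HPV-negative
head-and-neck tumours): gene-level activity is projected onto a
protein–protein interaction network, the most differentially active paths
in each case sample are extracted and tested against a permutation null,
and genes are scored by how central they are to the resulting significant
subnetwork ("TopNet"). Genes that are repeatedly central across samples —
the *central genes* — are the headline output, deliberately contrasted
with the top differentially expressed genes (DEGs).

## Per-sample node weights

For a case sample $j$, the signed per-gene fold change is
$\mathrm{lfc}_g = x_{gj} - \mathrm{ref}_g$ in log2 units, with
$\mathrm{ref}_g$ the control median (mean available). Raw $|\mathrm{lfc}|$
overemphasises low-expression genes, whose variance is larger. We
therefore regress $|\mathrm{lfc}_g|$ on the control reference expression
with a local-linear loess (tricube weights, span 0.75, predictions clipped
at zero) and keep only the positive excess:

$$ w_g = \max(|\mathrm{lfc}_g| - \widehat{E}|\mathrm{lfc}|(\mathrm{ref}_g),\, 0) + \varepsilon
 \quad \text{if } \mathrm{lfc}_g > 0, \qquad w_g = \varepsilon \text{ otherwise,}$$

in the "activated" mode (the "repressed" mode mirrors the sign gate). The
floor $\varepsilon = 10^{-4}$ keeps weights strictly positive, which the
path costs require; the sign gate means each mode sees only genes moving
in its direction. Weights are invariant to a global shift of the
expression matrix (fold changes cancel), which the tests assert.

Numerical choices: span 0.75 is the conventional loess default; the fit
falls back to the global mean $|\mathrm{lfc}|$ with a warning when the
control reference is constant; at least 30 genes are required for a
stable fit.

## Path activity and the permutation null

Weights are normalised by their maximum, $\hat w = w / \max w \in (0,1]$,
and an edge $(u,v)$ costs $1/\sqrt{\hat w_u \hat w_v}$ — the inverted
geometric mean, so a path is cheap only when *every* node on it carries
high weight. Terminals default to the top 5% of nodes by weight; for
every ordered terminal pair the minimum-cost Dijkstra path is a candidate
"differentially active path".

Significance: node weights are shuffled uniformly over the network
(topology fixed — the test asks whether the *placement* of weight matters),
edge costs rebuilt, and the same-pair shortest-path cost recomputed, 200
times by default. The plus-one estimator
$p = (1 + \#\{C_\text{perm} \le C_\text{obs}\})/(1 + B)$ never returns 0;
its minimum at $B = 200$ is $1/201 \approx 0.004975$. Pair p-values are
BH-adjusted and paths at adjusted $p \le 0.05$ form the TopNet.

Two calibration facts the test suite pins down:

* With terminals selected *by weight* (the pipeline default), observed
  paths are cheap under iid weights by construction — p-values are
  anti-conservative by design; that is the detection mechanism, not a
  defect.
* With terminal pairs chosen independently of the weights
  (`candidate_paths(pg, pairs = ...)`), the p-values are uniform. Because
  all pairs share the same $B$ permutations they are dependent, and the
  KS distance of ~200 pair p-values from $U(0,1)$ has a heavier tail than
  for independent draws (median ≈ 0.07 across seeds, occasionally above
  0.1).

## Ripple centrality and central genes

On the directed TopNet with $n$ nodes,
$r(v) = \sqrt{R_\text{out}(v)\, R_\text{in}(v)}/(n-1)$, where
$R_\text{out}/R_\text{in}$ count nodes reachable from / reaching $v$. A
node must both broadcast and receive to score; sources and sinks get 0, a
node on every path approaches 1. Per sample, the top 100 genes by $r$
(ties lexicographic) are kept; a sample with an empty TopNet counts as
non-significant. Across the significant samples, genes are ranked by
frequency (ties: mean centrality, then gene ID) and the top 100 are the
central genes, reported with `freq_fraction = frequency / #significant
samples`.

## Companion statistics

* **Differential expression** — Welch t or a documented moderated-t
  stand-in (pooled variance shrunk toward the median gene variance with
  prior df $d_0 = 4$); BH FDR; top-k selection filters at FDR ≤ 0.05
  *then* sorts by signed log2FC. Empirical-Bayes moderation itself is out
  of scope; the DEG list is the comparison baseline, not the headline.
* **Enrichment** — upper-tail hypergeometric ORA with set-size filters
  [10, 500] after intersecting sets with the background; Fisher overlap
  reports the sample odds ratio $(ad)/(bc)$ in a 20,000-gene universe by
  default (not printed in the motivating study but the unique round
  universe consistent with its published odds ratios), with the
  two-sided exact p by the point-probability rule. Redundancy reduction
  is greedy by ascending adjusted p with a membership-Jaccard cutoff of
  0.8 — a stand-in for ontology-graph semantic similarity, which needs
  the GO DAG.
* **Single-cell overlay** — per-gene one-way ANOVA across cell types,
  z-scoring of type means, and per-type
  $\log_2((\text{obs}+\delta)/(\text{exp}+\delta))$ expressed-gene
  fractions, $\delta = 10^{-6}$. "Expressed in a type" means z above 0,
  i.e. above the gene's own cross-type average — the source analyses never
  define it, so the threshold is exposed. Expected fractions use all
  matrix genes by default (`expected_over = "set"` for the alternative).
* **Classifier evaluation** — stratified 5-fold CV with a tiny inner grid
  search; AUROC by the Mann–Whitney identity, AUPRC as average precision,
  F1 at 0.5; percentile bootstrap CIs (resamples with one class redrawn);
  fast DeLong via placement values, with the single-AUROC variance
  matching a delete-one jackknife within 10% empirically. The learners
  are contract-level: decision-stump ensembles (bagged, extremely
  randomised, AdaBoost, gradient-boosted) and a ridge-logistic linear
  model standing in for a linear SVM — this environment ships no
  dedicated SVM/forest packages, and the module's point is the evaluation
  statistics. One visible consequence: stump *forests* with feature
  subsampling dilute a perfectly separating single feature slightly
  (AUROC ≳ 0.95 rather than exactly 1); the boosting learners, which scan
  every feature, achieve exactly 1.
* **Hubs and drugs** — degree ranking inside the confidence-filtered
  (strictly > 0.7 by convention) subnetwork induced on the central genes;
  top 10 by degree, lexicographic ties; up to 3 drugs per hub joined from
  a user-supplied table, `"no data"` otherwise.

## The synthetic world

`synthetic_spec()` states the world once; its defaults are a desk-scale
version of a 64 vs 437 unbalanced cohort:

| parameter | default | meaning |
|---|---|---|
| `n_case` / `n_control` | 16 / 48 | unbalanced two-group design |
| `n_genes` | 500 | network-scale gene panel |
| baseline | uniform log2 on [4, 8] | spans 4 log2 units so the loess trend is non-trivial |
| `noise_sd` | 0.5 | within-group sd at high expression; lower-expressed genes up to 2× noisier |
| `deg_fraction`, `deg_effect` | 0.1, 2 | 10% true DEGs, ±2 log2 shift (half up, half down) |
| `mediator_count`, `deg_noise` | 5, 0.1 | planted hubs with `|shift| ≤ 0.1` |

The network is a preferential-attachment backbone (m = 2) with each
mediator wired to ≥ 20 planted DEGs, so paths between differentially
expressed genes run through mediators. The generator emulates: unbalanced
groups, log-normal expression, expression-dependent noise, and
network-central mediators without fold change. It does **not** emulate
batch effects, count-level sampling noise, correlated co-expression
modules, or any tumour biology — so a green recovery test establishes
that the pipeline finds network mediators under its stated noise model,
not that it reproduces any cohort-specific gene list. The single-cell
generator draws negative-binomial counts with marker means elevated
2× in their own type; at elevation 1 it is an ANOVA-calibrated null.

On the default world (seed 7), all 5 planted mediators appear in the
final top-100 central genes and none in the top-100 DEG list — and the
same 5/5 vs 0/5 held for every other seed we tried. The DEG baseline is
itself calibrated (3–7% of null genes at p < 0.05) and recovers > 90% of
planted DEGs at FDR 0.05.

## Known limitations

* The moderated t is a stand-in, not empirical Bayes; with very few
  replicates its p-values are approximate.
* Shared permutations make pair p-values dependent; interpret the BH
  adjustment across pairs as pragmatic error control, not an exact FDR
  guarantee.
* Terminal-pair restriction (top 5% by weight) trades exhaustiveness for
  desk-scale runtime with 200 permutations; raise `terminal_fraction` for
  small networks.
* Ripple centrality uses unweighted reachability on the TopNet; edge
  costs do not propagate into the centrality.
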