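---
title: "Predicting gene dependencies from network-derived features"
author: "depnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gene dependencies from network-derived features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depnet)
```

## The problem

A gene dependency is a gene a cancer cell needs to keep growing:
knocking it out restricts growth or kills the cell. Genome-wide CRISPR
screens quantify this with a gene-effect score per (gene, cell line),
scaled so that the median of ubiquitously essential genes is $-1$ and
the median of nonessential genes is $0$; more negative means more
dependent. `depnet` asks whether a gene's position in a cancer
lineage's co-expression network predicts whether that lineage depends
on it, and which network properties carry that signal.

The pipeline has four stages, each exposed as package functions around
S4 data classes (`ExpressionMatrix`, `GeneNetwork`,
`GeneSetCollection`, `FeatureTable`, `DependencyScores`,
`DependencyLabels`):

1. **Network inference** (`estimateMINetwork`, `applyDPI`,
   `pruneNetwork`): a dense mutual-information (MI) graph over genes is
   estimated per lineage from expression, indirect edges are removed by
   the data-processing inequality (DPI), and edges below an MI cutoff
   are dropped.
2. **Feature engineering** (`networkFeatures`): four classes of
   per-gene features — classical topology (degree, average neighbour
   degree, sum of adjacent edge weights, betweenness, closeness);
   counts of first-degree neighbours in each of the 10 cancer-hallmark
   gene sets; hop-count shortest paths to every Cancer Gene Census
   (CGC) gene; and smallest-weight paths (minimum summed edge weight)
   to every CGC gene.
3. **Labeling** (`aggregateScores`, `binarizeDependency`): gene-effect
   scores are averaged over the lineage's cell lines and binarized at
   $-1$ (the tie is dependent).
4. **Modeling** (`crossvalF1`, `runModelZoo`, `ablateClasses`,
   `ablateSingleFeatures`, `permutationImportance`, `sweep*`):
   stratified 5-fold cross-validation scored with F1 on the dependent
   class, over a ten-classifier zoo, with ablation and importance
   analyses and robustness sweeps over the dependency cutoff and the
   MI pruning cutoff.

F1 is used because dependent genes are a small minority:
$F_1 = 2PR/(P+R)$ with precision $P = \mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$
and recall $R = \mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$, computed on the
positive (dependent) class; the all-zero case returns 0.

## Mutual-information estimation

No assumption is made about which MI estimator produced any published
cutoff; absolute MI scales differ across estimators, so cutoffs are
configuration, not constants. Two estimators ship:

* **binned** (default): equal-frequency discretization with the
  cube-root rule, $B = \lceil n^{1/3} \rceil$ bins per margin, plug-in
  entropy with the Miller–Madow correction, clipped at 0. With
  $B \sim n^{1/3}$ the $B^2$ joint cells stay well populated, so the
  bias correction works and independent vectors score near 0 (a
  $\sqrt n$ rule leaves several tenths of a nat of bias at
  $n = 1000$, which would swamp weak edges).
* **spearman_gaussian**: the Spearman correlation is mapped to the
  Pearson correlation of the underlying Gaussian copula
  ($\rho = 2\sin(\pi\rho_s/6)$) and converted by the closed form
  $-\tfrac12\log(1-\rho^2)$. It is monotone in $|\rho|$, unbounded as
  $|\rho|\to1$, and fast; it only sees monotone dependence.

DPI pruning flags, in every fully connected triple, the strictly
weakest edge when its weight is below the minimum of the other two
minus an additive `tolerance` (default 0, classic behaviour; `NA`
disables). Flags are computed on the input graph and removed
simultaneously, so the strongest edge of a triangle is never removed
and weights are never altered. The edge cutoff keeps
$w \ge \text{cutoff}$ — "below the cutoff" is removed, the boundary is
kept — and a per-lineage override map allows a stricter cutoff for
lineages whose networks would otherwise be unmanageably large.
Constant-expression genes are dropped from the lineage network with a
reported count.

## Feature conventions

* Centralities are computed unweighted on the pruned graph, in
  normalized form (betweenness by $\binom{n-1}{2}$; closeness
  per-component as reachable-count over summed hop distance). Isolated
  nodes score 0 everywhere.
* Smallest-weight paths default to literally minimizing the sum of MI
  weights (`mode = "raw"`); `mode = "inverse"` (cost $1/w$) is
  available for the conventional "strong edge = short distance"
  semantics. The two agree up to scale on uniform weights.
* Unreachable path targets get finite sentinels — $|V|$ for hop
  features, (sum of all edge costs) + 1 for weight features — large
  enough to sort beyond any achievable value while keeping models
  trainable; the policy is recorded on the `FeatureTable`.
* Genes with labels but no network features (dropped or isolated
  beyond reach) are excluded from the design matrix with a message,
  not zero-imputed: their features are undefined.
* Features are z-scored inside each training fold only; path and
  topology scales differ by orders of magnitude and several zoo models
  are scale-sensitive.

## The model zoo in R

The ten classifiers are backed by the R libraries a practitioner would
use, at library defaults unless overridden via `modelSpec()`
hyperparameters: `rpart` (decision tree, and depth-1 stumps inside an
in-package SAMME AdaBoost, 50 stumps — no installed R package provides
AdaBoost), `kernlab::gausspr` (Gaussian process), `class::knn`
(k = 5), `e1071::svm` (linear, RBF, and a linear variant with cost
$1/(10^{-4} n)$ mirroring SGD-trained linear SVMs),
`randomForest` (100 trees), and `glmnet`. Logistic regression uses
glmnet's own default usage — the lasso path with a cross-validated
penalty (prediction at `lambda.min`): with dozens of highly collinear
path columns per CGC gene, an unpenalized or fixed-ridge logistic fit
loses several F1 points to estimation variance, while the
cross-validated sparse fit concentrates on the informative columns.
The ridge classifier is least-squares on $\pm1$ targets with
$\lambda = 1/n$, thresholded at 0. Every stochastic step derives its
seed from the fold index and the `ModelSpec` seed, so fold scores are
bit-reproducible.

Evaluation is per lineage or pooled: `designMatrix()` concatenates
(gene, lineage) instances across per-lineage feature tables for the
pan-cancer setting. Grid evaluations (`runModelZoo`, the sweeps)
record per-cell failures — e.g. a cutoff that leaves fewer than $k$
instances of a class — as missing and continue.

## What the synthetic generator emulates

`generateSyntheticDataset()` plants a known feature-to-dependency
signal so recovery is testable end to end:

* **Network**: preferential attachment (`attachmentEdges = 2`), whose
  heavy-tailed degree distribution resembles inferred regulatory
  networks; weights uniform on an MI-like range $[0.5, 8]$.
* **Gene sets**: CGC-like (25) and ten hallmark-like sets (15 each)
  sampled disjointly without replacement, with probability
  $\propto \text{degree}^{\text{hubBias}}$ (default 1) since cancer
  genes are often hubs; `hubBias = 0` is the unbiased null.
* **Expression**: a linear-Gaussian structural scheme oriented by
  attachment age — an older gene regulates the younger genes that
  attached to it, so every gene has at most `attachmentEdges`
  regulators. Each gene is its regulators' weight-proportional mix
  plus Gaussian noise (sd `noiseSd`), standardized. The bounded
  in-degree is what guarantees detectable MI along every true edge; a
  random orientation can give a hub dozens of regulators, diluting
  each pairwise correlation below detectability and making edge
  recovery impossible in principle.
* **Dependency scores**: minus a linear combination of z-scored
  planted feature columns (defaults: degree with weight 1 and one
  hallmark neighbour count with weight 0.6 — strong enough to sit
  clearly above the noise floor, weak enough that the task is not
  trivial), flattened above its `signalQuantile` (0.3) quantile,
  plus per-gene scatter (`geneNoiseSd = 0.15`), affinely mapped so the
  signal median lands on 0 and its `dependencyFraction` (0.15)
  quantile on $-1$, then per-sample Gaussian noise
  (`noiseSd = 0.25`). The flattening and the two-point calibration
  mirror how gene-effect scores behave: nonessential genes score near
  0 regardless of network position, and the score scale is anchored at
  the nonessential median (0) and the essential median ($-1$). Without
  these two ingredients, averaging 30 samples shrinks the noise to
  $\approx 0.05$ and every binarization cutoff becomes equally
  learnable — the characteristic robustness curve (poor F1 for
  cutoffs near 0, a plateau below $-0.5$) cannot exist. Truth labels
  are recorded by running the labeling module itself on the generated
  scores, so binarization reproduces them exactly by construction.

Defaults (500 genes, 1 lineage, 30 samples) are the desk-scale study
conditions used by the acceptance checks. What passing recovery tests
does **not** show: the generator has no RNAseq count noise, batch
effects, copy-number confounding, or gene-identifier mismatch, and its
dependency signal really is a monotone function of two features —
real screens are noisier and their signal is distributed across many
correlated properties. Passing tests demonstrate the pipeline's
machinery (inference, features, labeling, evaluation) is correct and
sensitive, not that real-data F1 will match.

## Numerical choices and degenerate inputs

* Equal-frequency bin edges come from quantiles, so discretization is
  invariant to sample order; heavily tied vectors collapse duplicate
  edges and occupy fewer bins. Constant vectors yield MI 0 with a
  warning.
* Negative MI estimates (estimator bias) clip at 0.
* Stratified folds are dealt round-robin after a seeded shuffle per
  class; cross-validation refuses to run with fewer than $k$ instances
  of either class, with an actionable message.
* Z-scoring guards constant columns (scale 1), keeping sentinel-only
  columns harmless.
* `glmnet` needs two columns; single-feature designs are padded with a
  zero column.
* Sweeps sort and deduplicate their grids; a cutoff emptying the
  network or degenerating the labels is recorded as missing, never
  fatal.
* The dependency-cutoff grid defaults to $-1.5$ to $0.1$ in steps of
  0.1 (17 points); the extended variant appends 0.2 and 0.25 for the
  wider exploratory range.

## Problem sizes used by tests and the acceptance script

Unit tests run on graphs of 2–60 nodes against brute-force oracles
(exhaustive triangle enumeration for DPI, BFS and exhaustive
simple-path enumeration for path features, confusion-matrix arithmetic
for F1). The recovery experiments use the 500-gene default
configuration over 10 seeds; the pruning-sweep experiment re-infers
networks from a 100-gene, 100-sample dataset with structural noise 0.4
and the copula estimator, sweeping cutoffs 0–1 (the scale of that
estimator; absolute MI cutoffs do not transfer between estimators).
These sizes keep the full suite within a few minutes while leaving
every statistical check comfortably powered.

## Known limitations

* ARACNE-style inference here is the classic dense-MI + DPI + cutoff
  pipeline; bootstrap consensus networks and directed edge orientation
  are out of scope.
* The binned MI estimator is biased low for small samples even after
  correction; lineages near the 3-sample floor produce weak networks.
* Smallest-weight "raw" paths treat strong edges as *long*; that is
  the literal reading of summed-MI path length, and the inverse mode
  exists because the conventional semantics is arguably the opposite.
  Results for that feature class should be interpreted with the mode
  in mind.
* Per-gene expression summaries (mean, sd per lineage) are a minimal
  encoding of the "expression" feature set; richer encodings (e.g.
  per-sample profiles) would change the comparison between expression
  and network features.
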