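---
title: "Knowledge-slanted random forests: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-slanted random forests: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Small transcriptomic cohorts with tens of thousands of genes are a hostile
regime for random forests: with \(p \gg n\), most candidate-split draws are
noise genes, and with few samples a noise gene will often separate a
bootstrap sample perfectly by chance. When two clinical groups differ only
in a handful of genes — as with the two case subgroups of calcific aortic
valve stenosis, whose expression profiles largely overlap — the conventional
forest has little chance of finding them.

Protein–protein interaction (PPI) networks encode decades of accumulated
biology, and disease genes tend to cluster in network neighbourhoods. This
package slants the forest toward that knowledge: genes close in the network
to known disease ("seed") genes are offered to the trees more often.

## The model

**Stage 1 — network propagation.** Given an undirected weighted graph
\(G = (V, E)\) with confidence weights \(w_{ij} \in [0,1]\), form the
row-stochastic transition matrix \(A = D^{-1}W\) with
\(d_{ii} = \sum_j w_{ij}\), and iterate the random walk with restart (RWR)

\[
p^{(t+1)} = (1-\theta)\,A^{\top} p^{(t)} + \theta\, p^{(0)},
\]

where the prior \(p^{(0)}\) is 1 on seed genes and \(10^{-5}\) elsewhere,
and \(\theta\) is the restart probability. The fixed point
\(p^{*} = \theta\,(I - (1-\theta)A^{\top})^{-1} p^{(0)}\) scores every gene
by its network proximity to the seeds.

**Stage 2 — the slanted forest.** A classification forest where the `mtry`
candidate split variables at *every* node are drawn without replacement
with probability proportional to the (renormalised) \(p^{*}\). Uniform
weights recover the conventional random forest exactly — same code path,
equal probabilities. Everything else is standard CART/bagging: bootstrap
samples of size \(n\), Gini impurity splits at midpoints, growth to purity,
aggregation by majority vote.

The per-gene *selection frequency* — how many times each gene was chosen as
a split variable across the forest — doubles as the model's gene ranking.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `theta` | 0.3 | restart probability; the value recommended for STRING PPI networks. Larger values keep mass near the seeds, smaller values diffuse it. |
| `tol` | 1e-6 | L1 stopping threshold for the RWR iteration. |
| `seed_p0` / `background_p0` | 1 / 1e-5 | prior mass on seed / non-seed genes. Used unnormalised: the fixed point is linear in \(p^{(0)}\) and the weights are renormalised, so normalising the prior first would change nothing. |
| `ntree` | 500 | trees in the forest. |
| `mtry` | \(\lfloor\sqrt{p}\rfloor\) | candidate genes per node. The case study's headline setting is `forest_preset("cavs_default")` (`ntree = 500`, `mtry = 500`, i.e. roughly \(p/30\) of its 15,191 genes); `compare_modes()` carries that *fraction* over to simulated dimensions. |
| `min_node_size` | 1 | growth to purity, the classification default of reference forest implementations. |

## Numerical and algorithmic choices

* **Convergence norm.** The stopping rule uses the L1 norm of successive
  differences, matching probability-mass semantics. Because \(A\mathbf{1} =
  \mathbf{1}\), total mass \(\sum_i p_i^{(t)}\) is invariant; the
  implementation tracks the maximum drift (floating-point only, \(\le
  10^{-10}\)) as a self-check. Note that an L1 stop at `tol` bounds the
  distance to the fixed point by \(\mathrm{tol}\cdot(1-\theta)/\theta\),
  not by `tol` itself; `rwr_exact()` provides the dense-solve fixed point
  for validation at small scale.
* **Weighted sampling without replacement** is implemented with
  exponential keys (draw \(E_j/w_j\) with \(E_j \sim \mathrm{Exp}(1)\) and
  keep the `mtry` smallest), which reproduces *exactly* the distribution of
  successive draw-proportional-to-weight, remove, renormalise — at
  \(O(p \log \mathrm{mtry})\) per node. Zero-weight genes are never drawn.
* **Split search.** Thresholds at midpoints between consecutive distinct
  sorted values; Gini impurity by default (entropy available). Ties in
  impurity decrease break toward the lower gene index, then the lower
  threshold, so fits are exactly reproducible.
* **Vote ties** (possible with even `ntree`) break by class-level order —
  documented rather than randomised, again for reproducibility.
* **RNG discipline.** Each tree has its own stream derived from the master
  seed (a splitmix64 counter scramble), so results are bit-identical across
  platforms and growing more trees never reshuffles earlier ones. LOOCV
  folds and sweep cells similarly derive their seeds from the master seed
  and the fold index / cell values, making reports invariant to evaluation
  order.
* **Degenerate inputs.** Pure nodes, constant candidates, and nodes below
  `min_node_size` become leaves; a held-out sample whose class has no other
  representative is predicted as the training fold's single class (with a
  warning); metric ratios with zero denominators surface as `NaN` with a
  warning, never silently 0; RWR non-convergence at `max_iter` flags the
  result rather than failing, because weights from a slowly mixing network
  are still usable.
* **Missing genes.** Expression genes absent from the network receive the
  minimum positive propagation score before renormalisation (`floor`
  policy), so no gene silently vanishes from the classifier;
  `uniform_min` (the uniform share) is available when network coverage is
  poor.

## The evaluation protocol

`loocv()` implements leave-one-out cross-validation — the appropriate
protocol at \(n \approx 27\) — with per-class one-vs-rest sensitivity,
specificity and rank-based (Mann–Whitney) AUC on the vote fractions.
The multiclass AUC needs a definition choice; one-vs-rest on vote
fractions is standard and reproducible. `parameter_sweep()` aggregates
LOOCV accuracy over an `ntree` × `mtry` grid as mean ± sd over cells.
`anova_per_gene()` applies a classical equal-variance one-way ANOVA per
gene with no multiplicity adjustment by default (the raw \(p < 0.05\)
convention of differential-expression reporting); Benjamini–Hochberg is
available.

## What the synthetic studies emulate — and what they do not

`scenario_presets()` generates cohorts with the structure the method
assumes, sized like the motivating study (class sizes 10/9/8, \(p = 2000\)
genes so the suite runs at desk scale while preserving \(p \gg n\)):

* a **scale-free network** (preferential attachment, Beta(2,2) edge
  confidences) because PPI degree distributions are heavy-tailed;
* **informative genes planted as a connected neighbourhood** (a
  breadth-first ball), with seed genes overlapping them by 50% by default —
  emulating literature seeds lying near the true disease module;
* **two regimes**: `easy_two_class` (controls shifted by 3 sd on all 30
  informative genes — easily separable, where the conventional forest
  already performs well) and `hard_three_class` (the two case classes
  differ by 2 sd on only 10 genes out of 2000 — the overlapping regime
  where network knowledge should pay off);
* a **negative control**, `null_random_seeds`, with seed genes drawn at
  random disjoint from the informative set: the slant then carries no
  information and the slanted forest should match the conventional one.

Expression is simulated on a normalised Gaussian scale (the classifier is
distribution-agnostic and real pipelines feed it normalised values), not at
RNA-seq count level: no library sizes, dispersion, or normalisation
artefacts. Gene–gene expression correlation is not simulated either —
informative genes are network neighbours but statistically independent
given class. Passing tests therefore demonstrate the mechanism (propagation
concentrates sampling on the planted module; biased sampling finds small
overlapping signals that uniform sampling misses at \(p \gg n\)), not
performance on any particular real cohort.

## Worked example

```{r, eval = FALSE}
library(ksrf)

sim <- simulate_scenario("hard_three_class", seed = 11)
w   <- rwr_weights(sim)                 # RWR over the simulated network
fit <- ksrf(sim$x, sim$y, weights = w, ntree = 100, mtry = 67, seed = 3)
feature_frequency(fit, 10)              # gene ranking

cv_slanted <- loocv(sim$x, sim$y, weights = w,    ntree = 100, mtry = 67, seed = 3)
cv_uniform <- loocv(sim$x, sim$y, weights = NULL, ntree = 100, mtry = 67, seed = 3)
c(slanted = cv_slanted$accuracy, uniform = cv_uniform$accuracy)
```

`compare_modes()` wraps this replicate-level comparison; at the defaults
(20 replicates, `ntree = 100`, `mtry = p/30`) it shows a positive
slanted-minus-uniform gap on `hard_three_class`, a near-zero gap on
`null_random_seeds`, and ceiling performance for both modes on
`easy_two_class`.

## Known limitations

* The RWR uses \(A^\top\) with the row-normalised \(A = D^{-1}W\)
  (column-normalised propagation in effect), kept exactly as the method
  defines it; with symmetric \(W\) an alternative \(W D^{-1}\) convention
  would change scores but not the structure of the method.
* Selection frequency is the only importance measure (no permutation
  importance), and regression forests are out of scope.
* No identifier mapping between protein and gene namespaces: inputs must
  share one namespace.
* LOOCV at `ntree = 500` on tens of thousands of genes is compute-heavy by
  construction; the defaults here are sized for the simulated studies, and
  full-scale sweeps are an explicit user choice.
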