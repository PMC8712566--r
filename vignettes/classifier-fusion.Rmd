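---
title: "Fusing classifier ensembles with generalized Choquet integrals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing classifier ensembles with generalized Choquet integrals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choqfuse)
```

## The model

`choqfuse` treats binary classification of small clinical cohorts as a
two-stage problem: extract global network descriptors from multichannel
EEG, then combine the probabilistic outputs of several classical
classifiers with a fuzzy-measure-based aggregation operator.

### Fuzzy measure over classifiers

Let $x_1,\dots,x_n$ be the base classifiers and $g_i \in (0,1)$ the
*fuzzy density* of $x_i$ — its mean accuracy over stratified five-fold
cross-validation of the training split, interpreted as the degree of
trust in that model. A fuzzy measure (capacity) extends the densities to
coalitions monotonically with $g(\emptyset)=0$, $g(X)=1$. The Sugeno
$\lambda$-measure is the one-parameter family satisfying, on disjoint
sets,
$$g(U \cup W) = g(U) + g(W) + \lambda\, g(U)\, g(W),$$
and the normalization $g(X)=1$ fixes $\lambda$ as the unique root
$\lambda > -1$, $\lambda \neq 0$ of
$$1 + \lambda = \prod_{i=1}^n (1 + \lambda g_i).$$
Densities summing below 1 give $\lambda > 0$ (super-additive trust:
coalitions are worth more than their parts), above 1 give
$\lambda \in (-1,0)$, and exactly 1 the additive measure $\lambda = 0$.
For the nested level sets $U_i$ of the sorted score vector, the measure
follows the recursion
$$g(U_1) = g_{(1)}, \qquad
  g(U_{i+1}) = g(U_i) + g_{(i+1)} + \lambda\, g_{(i+1)}\, g(U_i).$$
Note the $g_{(i+1)}$ factor in the last term: it is required by the
disjoint-union rule above (with $W = \{x_{(i+1)}\}$), and without it the
chain cannot terminate at $g(X) = 1$ for the solved $\lambda$.

### The integrals

Given per-class scores $h(x_1),\dots,h(x_n)$ sorted non-increasingly
with $h(x_{n+1}) := 0$, the discrete Choquet integral is
$$C = \sum_{i=1}^n \big(h(x_{(i)}) - h(x_{(i+1)})\big)\, g(U_i).$$
The generalized (pre-aggregation) operators replace the product between
score increment and measure by a t-norm $M$; the package implements the
ten forms listed in `?aggregators` (`CM`, `CFM`, `CCM`, `CMC`, `CMMin`,
`CMMin2`, `CMinM`, `CD1`, `CD2`, `CD3`), plus OWA with linearly decaying
weights and the elementary baselines. Pre-aggregation deliberately
weakens the classical aggregation axioms — these operators keep
directional monotonicity but are in general neither idempotent nor
internal, which is why the test suite asserts internality only for the
classic integral.

### The feature pipeline

Each subject's epochs are band-pass filtered (zero-phase Hamming-window
FIR), directed connectivity is estimated as time-domain pairwise linear
Granger causality
$$F_{y \to x} = \ln\!\big(\sigma^2_{\text{restricted}} /
  \sigma^2_{\text{full}}\big)$$
on VAR fits with AIC lag selection, the directed matrix is symmetrized
(mean of the two directions by default; elementwise max by option) and
reduced to its maximum spanning tree by Kruskal's algorithm, and five
global tree metrics per band form the feature vector: maximal degree,
maximal betweenness centrality, leaf fraction $L/m$, diameter, and tree
hierarchy $T_h = L / (2\, m_{\text{edges}}\, BC_{\max})$.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| holdout fraction | 0.2 | the 80:20 protocol; 8 of 40 subjects held out |
| repetitions | 200 | 200 × 8 = 1,600 pooled predictions per grid cell |
| CV folds (densities) | 5 | stratified; folds must not exceed minority count |
| $\alpha$ sweep | $-10,-9.9,\dots,10$ | intersected with each family's range; for $\alpha>0$ families this is $0.1,\dots,10$ (100 values) |
| VAR max order | 20 | generous at 512 Hz; AIC picks the working order |
| FIR order | min(1.5 s of taps, a third of the epoch) | keeps the forward–backward pass conditioned on short epochs |
| $h_{(0)}$ for CD1–CD3 | 1 | scores are probabilities bounded by 1; `h0 = "first"` uses $h_{(1)}$ instead |

## Design choices made where the design was open

- **Chain alignment.** The measure chain is rebuilt for each class's
  score ordering (λ itself is permutation-invariant), so both class
  channels are aggregated under the same measure, each with its own
  level sets. Prediction is the argmax over fused class values; exact
  ties go to the class with the larger mean raw score, then the lower
  index. A positive-channel thresholding alternative was considered and
  rejected as the per-class form follows directly from aggregating
  "probability of belonging to each class" separately.
- **CD3's integrand** is parsed as the ratio
  $(h_{(i-1)} + h_{(i+1)})/h_{(i)}$; the alternative reading
  $h_{(i-1)} + h_{(i+1)}/h_{(i)}$ sits behind `cd3_ratio = "sum"`. Terms
  with $h_{(i)} = 0$ contribute 0 — every later sorted score is 0 too,
  so this is the telescoping-tail limit.
- **Domain clipping.** Arguments fed to $M$ can leave $[0,1]$ in the
  difference-type operators; they are clipped, the minimal total
  extension of a t-norm beyond its square.
- **Terminal snapping.** The recursion reaches $g(U_n) = 1$ only to
  solver tolerance ($\sim 10^{-12}$). Because boundary-steep t-norms
  (Yager with $\alpha < 1$ has unbounded slope at $y=1$) amplify that
  residual discontinuously, the chain's terminal value is set to exactly
  1 — which is what the normalization axiom states.
- **Numbering.** Only families printed with their formulas are
  registered by monograph index (8 and 12); everything else is addressed
  by name, and a user-supplied numbering map can extend the index. The
  Yager family *is* family 12; both names resolve to the same formula.
- **Root finding.** λ is bracketed by the sign of $\sum g_i - 1$
  (on $(-1,0)$ or $(0,\infty)$ with geometric expansion), bisected to
  width $10^{-12}$ and polished by Newton steps; the residual is checked
  against $10^{-10}$. Densities of exactly 0 are floored at $10^{-6}$
  with a warning, and cross-validated accuracies are capped at
  $1 - 10^{-6}$, keeping the measure well defined.
- **Kruskal by hand, metrics by igraph.** The maximum spanning tree is a
  direct Kruskal on descending weights with lexicographic tie-breaks, so
  the tree is deterministic even with tied weights; zero entries are
  treated as absent edges and a graph that cannot be spanned raises an
  error. Tree metrics (degree, betweenness, diameter) are delegated to
  igraph and cross-checked in the tests against an exhaustive
  path-walking oracle on enumerated trees. Betweenness is reported both
  raw and as the fraction of the $(m-1)(m-2)/2$ node pairs; the
  hierarchy uses the normalized fraction.
- **Band-resolved causality.** Spectral Granger causality is
  approximated by time-domain GC on band-filtered signals. This departs
  from autocovariance-based spectral factorization pipelines; it keeps
  the estimator elementary (two nested least squares) at the cost of
  some leakage between bands, acceptable here because the downstream
  features are coarse global tree statistics.

## What the synthetic generators emulate — and what they do not

`gen_var_cohort()` draws both classes from stable VAR(2) processes with
identical within-channel dynamics; the classes differ only in the set of
directed lag-1 couplings (4 vs 12 by default, strength 0.35 with ±15%
subject jitter), which is exactly the property the Granger pipeline is
built to detect. Defaults mirror the cohort dimensions: 20 + 20
subjects, 19 channels named after the 10–20 electrodes, 512 Hz, 25
epochs of 4,096 samples.

`gen_feature_table()` produces the 40 × 30 tree-metric table directly,
with Gaussian within-class noise around plausible 19-node tree values
and a configurable effect size per feature; the default shifts leaf
fraction and diameter by 0.8 sd in every band — a moderate global
reorganization of the tree backbone — leaving the other metrics at
chance.

`gen_classifier_scores()` uses a Gaussian copula on latent correctness:
classifier $i$ is correct when its latent normal coordinate falls below
the $\text{accuracy}_i$ quantile, so marginal accuracies are matched
exactly in expectation while error co-occurrence follows the copula
correlation. Confidences are mapped into the half-intervals
($0.5 + \mathrm{Beta}(5,2)/2$ when correct,
$0.5 - \mathrm{Beta}(2,5)/2$ when wrong) so that thresholding at 0.5
reproduces correctness by construction.

None of the generators model what real EEG brings: volume conduction,
ocular and muscular artifacts, non-stationarity, medication effects, or
the heavy-tailed confidence profiles of real classifiers. Passing tests
on synthetic data therefore demonstrate the *correctness of the
machinery* — measures solved, integrals summed, trees built, directions
recovered — not clinical-grade discrimination.

## Problem sizes used in tests and the acceptance script

The repeated-experiment checks run 20 repetitions on the 40-subject
table; the end-to-end replica simulates 40 subjects × 10 epochs of
1,024 samples over 8 channels at 128 Hz, extracts three bands
(θ, α, β — δ and γ are not cleanly representable at the scaled sampling
rate), and sweeps 2 operators × 2 families × 5 α values. Oracle suites
use 1,000 random instances; tree enumeration is exhaustive through
6-node trees (1,506 labelled trees) with seeded samples at 7 and 8
nodes, where full enumeration (16,807 and 262,144 trees) buys no
additional shape coverage.

## Known limitations

- Granger causality here is bivariate; indirect influences through third
  channels are not partialled out, as in any pairwise-GC design.
- The generalized operators are not calibrated probabilities; their
  fused values are scores for argmax comparison only (`CFM` is clamped
  at 1 by definition, others may exceed it).
- With `n = 1` classifier the measure degenerates ($g_1$ must be 1) and
  fusion reduces to that classifier's own argmax.
- EDF ingestion is not provided; signals interchange as CSV
  (channels × samples, electrode label first).
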