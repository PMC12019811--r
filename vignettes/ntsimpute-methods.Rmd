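---
title: "Imputing networked time series: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing networked time series: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntsimpute)
```

## The problem

A *networked time series* (NTS) couples a multivariate time series — a
`T x N x D` tensor of `D` features on `N` entities — with a sequence of `T`
weighted graphs over the same entities. Epidemic counts on a mobility
network, pollutant readings on a sensor-proximity graph and traffic flows on
a freeway network all have this shape. Both parts can be partially observed:
sensor failures hide feature entries, and when an entity drops out we
usually also lose its interactions, so edges go missing *together with*
node observations. `ntsimpute` jointly imputes both, treating feature
imputation and weighted link prediction as two coupled tasks that inform
each other: observed edges say which series should co-vary, and observed
series say which edges are plausible.

Masks are strictly binary throughout: 1 = observed, 0 = missing. Every
computation in the package ignores the value stored at a masked-out entry
(tests assert this by writing sentinels there), and everything that is
observed is passed through imputation untouched, exactly.

## The model

The model is a bidirectional variational autoencoder unrolled over sliding
windows of `dt` consecutive steps.

**Position embeddings.** Before training, every node at every step is
embedded by its random-walk-with-restart (RWR) profile against `L` anchor
nodes: the fixed point of `r = (1 - c) W r + c e_anchor` on the observed
graph of that step, with `W` the column-stochastic transition matrix
(`W[u, v] = A[u, v] / deg(v)`). These personalized-PageRank scores capture
global position: on a 6-cycle, where 1-WL color refinement — and hence any
message-passing network bounded by it — sees all nodes as identical, the RWR
scores against a single anchor already separate nodes by cycle distance.
The test suite checks this expressiveness gap directly, and checks the
power iteration against an independent dense linear solve.

**Encoder.** A 2-layer GRU consumes `[features, mask, positions]` per node
per step; its final state maps to the mean and log-variance of a diagonal
Gaussian posterior over a per-node latent `z` (one per window, used at every
decoder step), sampled by reparameterization.

**Decoder: three stages per step.** (1) a linear map of the previous hidden
state proposes an initial fill, and the *filler operator*
`mask * observed + (1 - mask) * prediction` keeps observed entries exact;
(2) node embeddings `U_t` (a linear map of `[filled, mask, positions,
H_prev]`) are paired with a unit-norm Bochner time encoding — interleaved
cos/sin at `k` learnable frequencies, invariant to time rescaling when
frequencies rescale inversely — and a two-layer MLP scores every node pair;
softplus makes weights nonnegative, the diagonal is zeroed and the matrix
symmetrized. One round of degree-normalized message passing on this
*predicted* graph then produces `H_graph`; (3) multi-head self-attention
over nodes on `[z, H_prev, H_graph, filled, mask]` plus an MLP head refines
the feature prediction, the filler is applied again, and a single-layer GRU
updates the per-node memory from `[z, output, mask, H_graph]`.

The backward replica runs the same architecture over the time-reversed
window with its own parameters; a merge MLP over both directions' hidden,
graph and output representations yields the final imputation.

**Loss.** Nine additive terms: the masked MAE of the merged output, the KL
divergence of each direction's posterior from the standard normal (weight
`beta`), masked MAEs of each direction's first- and third-stage raw
predictions, and each direction's link error (weight `gamma`). All feature
terms are evaluated on *observed* entries only; no artificial re-masking of
inputs is applied during training. The link term in the loss is a masked
RMSE — the Frobenius error per observed edge entry — so that the feature
and link tasks live on comparable scales regardless of how many edge slots
a window has; the evaluation metric reported to users remains the plain
masked Frobenius norm.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `c` (restart) | 0.15 | RWR teleport probability; standard PageRank value |
| `eps` | 1e-8 | power-iteration stopping tolerance (max norm) |
| `L` (anchors) | `min(N, ceiling(log2 N)^2)` | anchor-set size, following the position-aware GNN sizing convention; selection is by top observed weighted degree (deterministic, ties to smaller index) |
| `hidden_dim` | 64 | recurrent/graph width |
| `latent_dim` | 32 | posterior width |
| `time_pairs` | 8 | cos/sin frequency pairs; initialized log-spaced over periods 1..T steps |
| `beta` | 0.05 | KL weight; small, as in beta-VAE practice for reconstruction-dominated objectives |
| `gamma` | 1.0 | link-loss weight; with per-entry RMSE normalization the two tasks are comparable at 1 |
| `dt`, `stride` | 25, 25 | window length/stride; disjoint windows cover the sequence |
| `epochs`, `lr` | 300, 1e-3 | Adam without a scheduler |

All gradients come from the package's own tape-based reverse-mode
autodiff engine (`R/autodiff.R`), written for exactly the operations the
model needs; a test checks it against central finite differences at 1e-4
relative tolerance.

## Numerical choices and degenerate inputs

* **Dangling nodes** (zero weighted degree) would break probability
  conservation in RWR; their transition column restarts to the anchor, so
  every score vector sums to one even on an empty graph.
* **Transition orientation**: the column-stochastic convention is chosen so
  that mass conservation is an invariant one can test; for symmetric
  adjacencies it coincides with row normalization up to transposition.
* **Degree clamp**: message passing divides by `max(deg, 1)` so empty
  neighborhoods contribute nothing rather than dividing by zero.
* **Initial decoder memory** is drawn once per window per direction from
  `N(0, 1/hidden_dim)`. Both directions share one noise seed: on a
  palindromic window with mirrored parameters the backward pass then
  reproduces the reversed forward pass exactly, a symmetry the tests
  exploit (with zero time-encoder frequencies, since the Bochner code
  depends on the absolute timestamp, which cannot be palindromic).
* **Softplus link activation** keeps predicted weights nonnegative without
  a hard cutoff; the diagonal is structurally zero.
* **Masked-out entries** are replaced by zero before any linear algebra so
  `NA` sentinels cannot propagate; the filler restores observed values
  exactly afterwards.
* **Overlapping windows at imputation time** are reconciled by the
  arithmetic mean of the per-window predictions — unbiased and independent
  of window order; a tail not covered by the stride gets one extra window
  anchored at the sequence end.
* **Anchors are global per dataset** (not re-sampled per window) and the
  position tensor is computed once from the observed graphs, never updated
  from imputed ones.

## The synthetic generator

Real NTS benchmarks in this problem family are built from external data
(case counts on mobility graphs, air-quality stations, freeway sensors).
The generator reproduces their *statistical skeleton* so every stage of the
package is testable from code alone:

1. a static proximity base graph (random geometric with Gaussian-kernel
   weights by default; Erdos-Renyi and grid alternatives);
2. node signals as random loadings on `rank` smooth temporal factors
   (Gaussian-kernel-smoothed noise), mixed with the graph neighborhood so
   adjacent series correlate — the property that makes joint feature/edge
   imputation non-degenerate — then restandardized with additive noise;
3. dynamic edges: a base edge is present at `t` only while the RBF
   similarity `exp(-||x_u - x_v||^2 / (2 sigma^2))` of its endpoint signals
   exceeds the threshold `k`;
4. masking: feature entries hidden i.i.d. with probability `p`; edges
   hidden by the endpoint rule (any pair with a missing endpoint, which at
   `p = 0.25` hides `1 - 0.75^2 = 43.75%` of edge slots) or with a fixed
   0.7 drop probability among eligible pairs.

What the generator does **not** emulate: mechanistic epidemic dynamics,
heavy-tailed traffic regimes, non-stationary seasonal structure, spatially
correlated (non-i.i.d.) sensor dropout, and real-world measurement bias. A
passing recovery experiment therefore shows that the architecture can
exploit smooth temporal structure and graph-correlated signals under the
stated masking process — not that it matches published error tables on the
real datasets, which are outside what desk-scale synthetic data can show.

The reference fixture is `N = 12`, `T = 200`, `D = 1`, rank 3, `p = 0.25`,
endpoint rule, dynamics threshold `k = 0.3`, seed 0. For the recovery
experiment the model is scaled to the fixture (`hidden_dim = 16`,
`latent_dim = 8`, `time_pairs = 4`, `mlp_hidden = 16`, window 25/stride
25, 300 epochs), sizes chosen once so a full 5-seed experiment trains in
minutes on one CPU core; the acceptance checks compare the trained model
against the node-mean baseline (features) and the all-zeros predictor
(edges) on the hidden entries.

## Decisions where the design was genuinely open

* **Stage-loss targets.** The first- and third-stage loss terms use the raw
  stage predictions against observed entries. Applying them to the
  filler *output* would make those terms identically zero (the filler
  copies observed entries), so the raw-prediction reading is the only one
  that yields a meaningful training signal, and it is the one consistent
  with the worked one-entry example in the tests.
* **Message-passing design.** A single round of degree-normalized
  weighted aggregation with a residual linear term
  (`relu(D^-1 A U W1 + U W2 + b)`), the smallest design that is
  permutation-equivariant and uses the predicted weights.
* **Directions share nothing.** Forward and backward replicas have fully
  separate parameters (encoder included); sharing is a plausible variant
  but the replicated reading is the literal one.
* **Latent usage.** One latent per node per window, broadcast to all
  decoder steps, since the decoder references `z` without a time index.
* **Absent edges vs missing edges.** The bundle format distinguishes
  "observed weight zero" from "unobserved" explicitly (manifest rule
  `absent=zero` with a separate missing-edge list), because a raw edge
  list cannot distinguish the two and the distinction changes both the
  loss and the evaluation.
* **Feature-mask granularity.** Feature entries are hidden i.i.d. per
  entry; a node counts as missing for the endpoint rule when all its
  features are hidden (identical notions at `D = 1`). Block (per
  node-time) masking is a config stub left unimplemented.
* **Graphs are undirected** by default; all target applications use
  proximity or mobility graphs with symmetric weights. Directed bundles
  skip the symmetrization but share every other code path.

## Known limitations

Training is CPU-bound R: fine for tens of nodes and a few hundred steps,
not for the thousands-of-sensors regime. Self-attention is quadratic in
`N` per step. No minibatch shuffling, learning-rate schedules or gradient
clipping; divergence aborts with the epoch index. Forecasting beyond the
window is not exposed (the time encoder extrapolates, but no API does).
Irregular sampling grids, multigraphs and categorical features are out of
scope.

## Problem sizes used by the shipped experiments

Unit tests run on bundles of 4-10 nodes and 6-30 steps and finish in
seconds. The recovery experiment trains the fixture five times for 300
epochs (about two minutes each on one core); the acceptance script runs
one such training plus the RWR oracle comparison (100 random graphs up to
50 nodes) and a 35-node/200-step masking-rate check.
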