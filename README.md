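# ntsimpute

Joint imputation of missing **node features** and missing **weighted
edges** in networked time series.

A networked time series (NTS) is a multivariate time series
`X ∈ R^{T×N×D}` whose `N` entities are the nodes of a time-varying
weighted graph `A_1, …, A_T ∈ R^{N×N}`. In the applications this package
targets — epidemic counts on mobility networks, air-quality stations on
proximity graphs, traffic sensors on road networks — observations drop out
(binary mask `M^X`), and when an entity drops out its interactions usually
vanish with it (edge mask `M^A`). Standard multivariate-series imputers
ignore the graph; standard graph imputers assume the graph is static and
fully known. `ntsimpute` handles the joint problem.

## The model

A bidirectional variational autoencoder over sliding windows:

* **RWR position embeddings.** Each node is embedded by its
  random-walk-with-restart profile against `L` anchor nodes — the fixed
  point of `r = (1−c) W r + c e_anchor` with `W` column-stochastic — on
  the observed graph of each step. These personalized-PageRank scores
  separate nodes that 1-WL-bounded message passing cannot (e.g. all nodes
  of a cycle), giving the encoder global structural position.
* **Recurrent variational encoder.** A 2-layer GRU over
  `[X̃, M, R]` yields a diagonal-Gaussian posterior over a per-node latent
  `z`.
* **Three-stage decoder per step.** (1) initial linear fill, with the
  filler operator `M ⊙ X̃ + (1−M) ⊙ Ŷ` preserving observed entries exactly;
  (2) weighted link prediction over all node pairs using unit-norm Bochner
  time encodings, then degree-normalized message passing *on the predicted
  graph*; (3) self-attention over nodes plus an MLP head for the refined
  fill, and a GRU memory update.
* **Bidirectional merge.** A forward and a backward replica (separate
  parameters) are merged per step by an MLP.

Training minimizes a nine-term objective: masked MAE of the merged output,
`β`·KL for both posteriors, masked MAEs of both directions' stage-1 and
stage-3 predictions, and `γ`·link error on observed edge entries — an
evidence-lower-bound-style multi-task objective optimized with Adam on the
package's own reverse-mode autodiff engine (no external deep-learning
framework is used).

The package also ships a synthetic NTS generator (smooth correlated node
signals on a proximity graph, RBF-thresholded dynamic edges, endpoint-rule
edge masking), a masked evaluation harness (MAE / MSE / MRE / Frobenius
link error), a node-mean baseline, and a small CLI
(`inst/scripts/ntsimpute.R`) wiring `simulate → train → impute → evaluate`.

## Worked example

```r
library(ntsimpute)

gt <- generate_nts(generator_config(N = 8, T = 60, seed = 1))
b  <- gt$bundle            # partially observed NTS
b
#> <nts_bundle> T=60 N=8 D=1 (undirected)
#>   features observed: 71.0%  edges observed: 57.1%

fit <- nts_train(b,
  model_config(hidden_dim = 16, latent_dim = 8, time_pairs = 4,
               mlp_hidden = 16, seed = 1),
  train_config(epochs = 150, dt = 20, stride = 20, seed = 1))
fit$log$total[c(1, 75, 150)]
#> epoch   1  total 6.307
#> epoch  75  total 1.663
#> epoch 150  total 1.316

imp <- nts_impute(b, fit)
ev  <- list(features = gt$eval_feature_mask, edges = gt$eval_edge_mask)
evaluate_imputation(imp, gt$truth, ev, b)$mae
#> model MAE 0.261  (node-mean baseline: 0.848)
```

The training total falls as the model learns; the masked MAE is computed
only on deliberately hidden entries, and 0.26 vs 0.85 means the model
recovers hidden signal values about three times more accurately than
imputing each node's sequence mean. On the same hidden set the predicted
adjacency beats the all-zeros predictor (Frobenius error 10.8 vs 12.6).
Observed entries pass through both outputs untouched, exactly.

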