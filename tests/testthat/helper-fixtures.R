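# Small fixtures built in code; all seeded.

tiny_truth <- function(N = 5, T = 8, D = 1, seed = 0) {
  gt <- generate_nts(generator_config(N = N, T = T, D = D, seed = seed,
                                      threshold = 0, edge_rule = "none",
                                      node_missing_rate = 0))
  gt
}

tiny_bundle <- function(N = 5, T = 8, D = 1, seed = 0, p = 0.25,
                        edge_rule = "endpoint") {
  generate_nts(generator_config(N = N, T = T, D = D, seed = seed,
                                node_missing_rate = p,
                                edge_rule = edge_rule))$bundle
}

tiny_model <- function(bundle, dh = 6, dz = 3, k = 2, mlp = 5, seed = 1,
                       L = 3) {
  mc <- model_config(hidden_dim = dh, latent_dim = dz, time_pairs = k,
                     mlp_hidden = mlp, heads = 2, seed = seed)
  d <- nts_dim(bundle)
  model <- init_model_params(mc, n_features = unname(d[3]), n_anchors = L,
                             t_ref = unname(d[1]))
  anchors <- select_anchors(bundle, L = L)
  positions <- build_position_tensor(bundle, anchors)
  list(model = model, anchors = anchors, positions = positions, config = mc)
}

# Dense linear-solve RWR oracle, independent of the power iteration.
rwr_oracle <- function(adjacency, anchor, c) {
  n <- nrow(adjacency)
  W <- ntsimpute:::.rwr_transition(adjacency, anchor)
  e <- numeric(n); e[anchor] <- 1
  as.vector(solve(diag(n) - (1 - c) * W, c * e))
}

random_weighted_graph <- function(n, p_edge = 0.4) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (stats::runif(1) < p_edge) {
      w <- stats::runif(1, 0.1, 2)
      A[i, j] <- w; A[j, i] <- w
    }
  }
  A
}

cycle_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- 1; A[j, i] <- 1
  }
  A
}
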