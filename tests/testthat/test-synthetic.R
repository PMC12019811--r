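test_that("disabled thresholds give a fully observed bundle with static
           support equal to the base graph", {
  gt <- generate_nts(generator_config(N = 8, T = 15, seed = 0,
                                      node_missing_rate = 0,
                                      edge_rule = "none", threshold = 0))
  expect_true(all(gt$bundle$feature_mask == 1))
  expect_true(all(gt$bundle$edge_mask == 1))
  expect_equal(sum(gt$eval_feature_mask), 0)
  supp <- gt$truth$adjacency[1, , ] != 0
  for (t in 2:15) expect_identical(gt$truth$adjacency[t, , ] != 0, supp)
  rep <- validate_bundle(gt$bundle)
  expect_true(all(rep$pass))
})

test_that("generation is seed-deterministic and a huge threshold removes all
           edges", {
  g1 <- generate_nts(generator_config(N = 6, T = 10, seed = 3))
  g2 <- generate_nts(generator_config(N = 6, T = 10, seed = 3))
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$bundle$features, g2$bundle$features)
  expect_identical(g1$eval_feature_mask, g2$eval_feature_mask)

  g3 <- generate_nts(generator_config(N = 6, T = 10, seed = 3,
                                      threshold = 1e9))
  expect_true(all(g3$truth$adjacency == 0))
})

test_that("radial-basis similarity matches its closed form and decreases
           with distance", {
  expect_equal(rbf_similarity(c(1, 2), c(1, 2), 0.7), 1)
  s <- 1.3
  x <- c(0, 0); y <- c(sqrt(2) * s, 0)   # squared distance 2 sigma^2
  expect_equal(rbf_similarity(x, y, s), exp(-1), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    a <- stats::rnorm(3); d1 <- stats::runif(1, 0.1, 1)
    d2 <- d1 + stats::runif(1, 0.1, 1)
    expect_gt(rbf_similarity(a, a + c(d1, 0, 0), 1),
              rbf_similarity(a, a + c(d2, 0, 0), 1))
  }
  expect_error(rbf_similarity(1, 2, 0), "sigma")
})

test_that("endpoint masking hides exactly the edges incident to hidden
           nodes, and eval masks complement observation masks", {
  gt <- generate_nts(generator_config(N = 10, T = 30, seed = 1,
                                      node_missing_rate = 0.3))
  b <- gt$bundle
  node_missing <- apply(b$feature_mask, c(1, 2), max) == 0
  for (t in c(1, 10, 25)) {
    for (u in 1:10) {
      inc <- b$edge_mask[t, u, -u]
      if (node_missing[t, u]) {
        expect_true(all(inc == 0))
      } else {
        other_missing <- node_missing[t, -u]
        expect_identical(unname(inc == 0), unname(other_missing))
      }
    }
  }
  expect_true(all(gt$eval_feature_mask + b$feature_mask == 1))
  expect_true(all(gt$eval_edge_mask + b$edge_mask == 1))
})

test_that("p = 0 hides nothing under the endpoint rule", {
  truth <- tiny_truth(N = 6, T = 10, seed = 2)$truth
  m <- apply_masks(truth, p = 0, edge_rule = "endpoint", seed = 5)
  expect_true(all(m$bundle$feature_mask == 1))
  expect_true(all(m$bundle$edge_mask == 1))
})

test_that("the hidden-feature fraction concentrates at p", {
  truth <- list(features = array(stats::rnorm(100 * 10 * 10),
                                 c(100, 10, 10)),
                adjacency = array(0, c(100, 10, 10)),
                timestamps = 0:99)
  m <- apply_masks(truth, p = 0.25, edge_rule = "none", seed = 8)
  n <- length(truth$features)   # 10^4 entries
  frac <- mean(m$bundle$feature_mask == 0)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("drop70 hides about 70% of the endpoint-eligible edges", {
  truth <- list(features = array(stats::rnorm(200 * 12), c(200, 12, 1)),
                adjacency = array(1, c(200, 12, 12)),
                timestamps = 0:199)
  m <- apply_masks(truth, p = 0.25, edge_rule = "drop70", seed = 4)
  me <- apply_masks(truth, p = 0.25, edge_rule = "endpoint", seed = 4)
  eligible <- me$eval_edge_mask == 1
  frac <- sum(m$eval_edge_mask[eligible]) / sum(eligible)
  expect_lt(abs(frac - 0.7), 0.03)
  # drop70 never hides an edge the endpoint rule would not
  expect_true(all(m$eval_edge_mask <= me$eval_edge_mask))
})

test_that("coupled signals correlate more between neighbors than between
           non-adjacent pairs", {
  gt <- generate_nts(generator_config(N = 12, T = 200, seed = 0,
                                      node_missing_rate = 0,
                                      edge_rule = "none", threshold = 0))
  x <- gt$truth$features[, , 1]
  base <- gt$truth$adjacency[1, , ] != 0
  cors_nb <- c(); cors_far <- c()
  for (u in 1:11) for (v in (u + 1):12) {
    r <- abs(stats::cor(x[, u], x[, v]))
    if (base[u, v]) cors_nb <- c(cors_nb, r) else cors_far <- c(cors_far, r)
  }
  expect_gt(mean(cors_nb), mean(cors_far))
})
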