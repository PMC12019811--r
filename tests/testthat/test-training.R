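test_that("masked MAE follows its definition and guards the denominator", {
  expect_equal(masked_mae(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  expect_equal(masked_mae(c(1, 3, 2), c(1, 2, 4), c(1, 1, 1)), 1)
  expect_equal(masked_mae(c(9, 9), c(1, 2), c(0, 0)), 0)
  expect_error(masked_mae(1:2, 1:3, 1:3), "shape")
})

test_that("masked Frobenius error follows its definition and ignores
           masked-out entries", {
  a <- array(3, c(1, 2, 2)); p <- array(1, c(1, 2, 2))
  m <- array(0, c(1, 2, 2)); m[1, 1, 2] <- 1
  expect_equal(link_frobenius(p, a, m), 2)
  expect_equal(link_frobenius(a, a, array(1, c(1, 2, 2))), 0)
  p2 <- p; p2[1, 2, 1] <- 1e6   # masked-out entry
  expect_equal(link_frobenius(p2, a, m), link_frobenius(p, a, m))
})

test_that("loss vanishes at a perfect fit and reproduces the hand-computed
           one-entry example", {
  lab <- list(features = array(2, c(1, 1, 1)),
              feature_mask = array(1, c(1, 1, 1)))
  perfect <- list(y_final = array(2, c(1, 1, 1)),
                  y1_f = array(2, c(1, 1, 1)), y1_b = array(2, c(1, 1, 1)),
                  y3_f = array(2, c(1, 1, 1)), y3_b = array(2, c(1, 1, 1)),
                  mu_f = matrix(0, 1, 2), lv_f = matrix(0, 1, 2),
                  mu_b = matrix(0, 1, 2), lv_b = matrix(0, 1, 2))
  for (bg in list(c(0, 0), c(0.5, 2), c(1, 1))) {
    l0 <- compute_loss(perfect, lab, beta = bg[1], gamma = bg[2])
    expect_equal(l0$total, 0)
  }

  ex <- list(y_final = array(1.8, c(1, 1, 1)),
             y1_f = array(1.0, c(1, 1, 1)), y1_b = array(1.2, c(1, 1, 1)),
             y3_f = array(1.5, c(1, 1, 1)), y3_b = array(1.6, c(1, 1, 1)))
  l <- compute_loss(ex, lab, beta = 0, gamma = 0)
  expect_equal(l$final_mae, 0.2)
  expect_equal(l$stage1_mae_f, 1.0)
  expect_equal(l$stage1_mae_b, 0.8)
  expect_equal(l$stage3_mae_f, 0.5)
  expect_equal(l$stage3_mae_b, 0.4)
  expect_equal(l$total, 2.9)
  expect_error(compute_loss(ex, lab, beta = -1), "nonnegative")
})

test_that("doubling beta changes the total by exactly beta * (kl_f + kl_b)", {
  lab <- list(features = array(1, c(2, 2, 1)),
              feature_mask = array(1, c(2, 2, 1)))
  set.seed(2)
  out <- list(y_final = array(stats::rnorm(4), c(2, 2, 1)),
              y1_f = array(0, c(2, 2, 1)), y1_b = array(0, c(2, 2, 1)),
              y3_f = array(0, c(2, 2, 1)), y3_b = array(0, c(2, 2, 1)),
              mu_f = matrix(stats::rnorm(4), 2), lv_f = matrix(0.3, 2, 2),
              mu_b = matrix(stats::rnorm(4), 2), lv_b = matrix(-0.2, 2, 2))
  l1 <- compute_loss(out, lab, beta = 0.1, gamma = 0)
  l2 <- compute_loss(out, lab, beta = 0.2, gamma = 0)
  expect_equal(l2$total - l1$total, 0.1 * (l1$kl_f + l1$kl_b),
               tolerance = 1e-12)
})

test_that("training logs satisfy the loss additivity ledger and epochs=1
           logs exactly one record", {
  b <- tiny_bundle(N = 5, T = 12, seed = 1)
  mc <- model_config(hidden_dim = 6, latent_dim = 3, time_pairs = 2,
                     mlp_hidden = 5, anchor_count = 3, seed = 0)
  fit <- nts_train(b, mc, train_config(epochs = 8, dt = 6, stride = 6,
                                       seed = 0))
  expect_equal(nrow(fit$log), 8)
  for (i in seq_len(nrow(fit$log))) {
    r <- fit$log[i, ]
    expect_equal(r$total,
                 r$final_mae + r$beta * (r$kl_f + r$kl_b) +
                   r$stage1_mae_f + r$stage1_mae_b +
                   r$gamma * (r$link_frob_f + r$link_frob_b) +
                   r$stage3_mae_f + r$stage3_mae_b,
                 tolerance = 1e-10)
    expect_true(all(r[, c("final_mae", "kl_f", "kl_b", "stage1_mae_f",
                          "stage1_mae_b", "link_frob_f", "link_frob_b",
                          "stage3_mae_f", "stage3_mae_b")] >= 0))
  }
  fit1 <- nts_train(b, mc, train_config(epochs = 1, dt = 6, stride = 6,
                                        seed = 0))
  expect_equal(nrow(fit1$log), 1)
})

test_that("training is deterministic under a fixed seed", {
  b <- tiny_bundle(N = 4, T = 8, seed = 2)
  mc <- model_config(hidden_dim = 5, latent_dim = 3, time_pairs = 2,
                     mlp_hidden = 4, anchor_count = 2, seed = 1)
  tc <- train_config(epochs = 3, dt = 4, stride = 4, seed = 7)
  f1 <- nts_train(b, mc, tc)
  f2 <- nts_train(b, mc, tc)
  expect_equal(f1$log$total, f2$log$total, tolerance = 1e-6)
  expect_identical(f1$model$theta, f2$model$theta)
})

test_that("autodiff gradients match central finite differences", {
  gt <- generate_nts(generator_config(N = 4, T = 6, seed = 3))
  b <- gt$bundle
  mc <- model_config(hidden_dim = 6, latent_dim = 3, time_pairs = 2,
                     mlp_hidden = 5, heads = 2, seed = 1)
  anchors <- select_anchors(b, L = 3)
  positions <- build_position_tensor(b, anchors)
  windows <- make_windows(b, 3, 3)
  model <- init_model_params(mc, 1, 3, t_ref = 6)
  data <- ntsimpute:::.prepare_batch(
    windows, ntsimpute:::.positions_for_windows(windows, positions), TRUE)
  noise <- ntsimpute:::.draw_noise(7, data$WN, mc$hidden_dim, mc$latent_dim)
  theta <- model$theta
  fw <- ntsimpute:::.loss_forward(theta, mc, data, 0.05, 1.0, noise)
  ntsimpute:::ad_backward(fw$tape, fw$total)
  lossfun <- function(th)
    ntsimpute:::.loss_forward(th, mc, data, 0.05, 1.0, noise)$breakdown$total
  set.seed(9)
  h <- 1e-5
  for (rep in 1:10) {
    nm <- sample(names(theta), 1)
    i <- sample(length(theta[[nm]]), 1)
    tp <- theta; tp[[nm]][i] <- tp[[nm]][i] + h
    tm <- theta; tm[[nm]][i] <- tm[[nm]][i] - h
    fd <- (lossfun(tp) - lossfun(tm)) / (2 * h)
    ag <- ntsimpute:::ad_grad(fw$tape, nm)[i]
    expect_lt(abs(fd - ag) / max(abs(fd), abs(ag), 1e-8), 1e-4)
  }
})

test_that("the loss ignores values stored at masked-out entries", {
  b <- tiny_bundle(N = 5, T = 8, seed = 4)
  b2 <- b
  b2$features[b2$feature_mask == 0] <- 1234.5   # arbitrary finite sentinel
  mc <- model_config(hidden_dim = 5, latent_dim = 3, time_pairs = 2,
                     mlp_hidden = 4, anchor_count = 2, seed = 0)
  tc <- train_config(epochs = 2, dt = 4, stride = 4, seed = 0)
  f1 <- nts_train(b, mc, tc)
  f2 <- nts_train(b2, mc, tc)
  expect_identical(f1$log, f2$log)
})

test_that("imputation conserves observed entries for untrained parameters
           and is the identity on a fully observed bundle", {
  gt <- tiny_truth(N = 5, T = 8, seed = 5)
  full <- gt$bundle
  tmf <- tiny_model(full)
  fit_full <- structure(list(model = tmf$model, anchors = tmf$anchors,
                             train_config = train_config(dt = 4, stride = 4)),
                        class = "nts_fit")
  imp_full <- nts_impute(full, fit_full)
  expect_identical(imp_full$features, full$features)
  expect_equal(sum(imp_full$imputed_features), 0)

  b <- tiny_bundle(N = 5, T = 8, seed = 5)
  tm <- tiny_model(b, seed = 99)   # random untrained parameters
  fit <- structure(list(model = tm$model, anchors = tm$anchors,
                        train_config = train_config(dt = 4, stride = 4,
                                                    seed = 3)),
                   class = "nts_fit")
  imp <- nts_impute(b, fit)
  obs <- b$feature_mask == 1
  expect_identical(imp$features[obs], b$features[obs])
  eobs <- b$edge_mask == 1
  expect_identical(imp$adjacency[eobs], b$adjacency[eobs])
})

test_that("uncovered tails are still imputed via the extra end window", {
  b <- tiny_bundle(N = 4, T = 10, seed = 6)
  tm <- tiny_model(b)
  fit <- structure(list(model = tm$model, anchors = tm$anchors,
                        train_config = train_config(dt = 4, stride = 4)),
                   class = "nts_fit")
  imp <- nts_impute(b, fit)   # windows at 0,4 leave t=8,9 to the end window
  expect_true(all(is.finite(imp$features)))
})
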