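#' Masked mean absolute error
#'
#' \code{sum(mask * |label - pred|) / max(sum(mask), 1)}: entries with mask 0
#' contribute nothing, and an all-zero mask returns 0 rather than dividing by
#' zero. Values stored at masked-out entries (including \code{NA}) are
#' ignored.
#'
#' @param pred,label,mask equally shaped numeric arrays; \code{mask} binary.
#' @return scalar.
#' @export
masked_mae <- function(pred, label, mask) {
  if (!.same_shape(pred, label) || !.same_shape(pred, mask))
    stop("masked_mae: shapes must match")
  d <- abs(label - pred)
  d[mask == 0] <- 0
  d[!is.finite(d)] <- 0
  sum(d) / max(sum(mask), 1)
}

#' Masked Frobenius link-prediction error
#'
#' \code{sqrt(sum(edge_mask * (obs - pred)^2))} restricted to observed (or
#' evaluated) edge entries; entries with mask 0 never contribute.
#'
#' @param pred_adj,obs_adj,edge_mask equally shaped numeric arrays.
#' @return scalar \code{>= 0}.
#' @export
link_frobenius <- function(pred_adj, obs_adj, edge_mask) {
  if (!.same_shape(pred_adj, obs_adj) || !.same_shape(pred_adj, edge_mask))
    stop("link_frobenius: shapes must match")
  d <- (obs_adj - pred_adj)^2
  d[edge_mask == 0] <- 0
  d[!is.finite(d)] <- 0
  sqrt(sum(d))
}

.kl_gauss <- function(mu, lv) {
  if (is.null(mu)) return(0)
  0.5 * mean(mu^2 + exp(lv) - lv - 1)
}

# Normalized link loss term used in training: masked RMSE over observed edge
# entries, so the feature and link tasks live on comparable scales.
.link_rmse <- function(pred, obs, mask) {
  cnt <- sum(mask)
  if (cnt == 0) return(0)
  d <- (obs - pred)^2
  d[mask == 0] <- 0
  d[!is.finite(d)] <- 0
  sqrt(sum(d) / cnt)
}

#' Assemble the nine-term training loss
#'
#' The objective is the sum of: the masked MAE of the final (merged)
#' imputation, \code{beta} times the KL divergence of each direction's
#' posterior from the standard normal, the masked MAE of each direction's
#' first-stage prediction, \code{gamma} times each direction's link error
#' (masked RMSE over observed edge entries), and the masked MAE of each
#' direction's third-stage prediction. All feature terms are evaluated
#' against observed entries only.
#'
#' @param outputs list with \code{y_final}, \code{y1_f}, \code{y1_b},
#'   \code{y3_f}, \code{y3_b} (arrays shaped like the labels), \code{a_f},
#'   \code{a_b} (adjacency arrays, optional), and posterior moments
#'   \code{mu_f}, \code{lv_f}, \code{mu_b}, \code{lv_b} (optional).
#' @param labels list with \code{features}, \code{feature_mask}, and
#'   optionally \code{adjacency}, \code{edge_mask}.
#' @param beta KL weight, \code{>= 0}.
#' @param gamma link-loss weight, \code{>= 0}.
#' @return a \code{nts_loss} list: every term, the weights and \code{total}.
#' @export
compute_loss <- function(outputs, labels, beta = 0.05, gamma = 1.0) {
  if (beta < 0 || gamma < 0) stop("beta and gamma must be nonnegative")
  x <- labels$features; m <- labels$feature_mask
  lb <- list(
    final_mae = masked_mae(outputs$y_final, x, m),
    kl_f = .kl_gauss(outputs$mu_f, outputs$lv_f),
    kl_b = .kl_gauss(outputs$mu_b, outputs$lv_b),
    stage1_mae_f = masked_mae(outputs$y1_f, x, m),
    stage1_mae_b = masked_mae(outputs$y1_b, x, m),
    link_frob_f = if (is.null(outputs$a_f)) 0 else
      .link_rmse(outputs$a_f, labels$adjacency, labels$edge_mask),
    link_frob_b = if (is.null(outputs$a_b)) 0 else
      .link_rmse(outputs$a_b, labels$adjacency, labels$edge_mask),
    stage3_mae_f = masked_mae(outputs$y3_f, x, m),
    stage3_mae_b = masked_mae(outputs$y3_b, x, m),
    beta = beta, gamma = gamma)
  lb$total <- lb$final_mae + beta * (lb$kl_f + lb$kl_b) +
    lb$stage1_mae_f + lb$stage1_mae_b +
    gamma * (lb$link_frob_f + lb$link_frob_b) +
    lb$stage3_mae_f + lb$stage3_mae_b
  structure(lb, class = "nts_loss")
}

#' Training configuration
#'
#' @param epochs number of optimization epochs.
#' @param learning_rate Adam step size.
#' @param batch windows per optimization step (\code{Inf} = full batch).
#' @param dt window length.
#' @param stride window stride (defaults to \code{dt}: disjoint cover).
#' @param beta KL weight.
#' @param gamma link-loss weight.
#' @param seed seed for noise draws during training.
#' @param patience early-stopping patience on the validation MAE when a
#'   validation set is supplied to \code{\link{nts_train}}; \code{Inf}
#'   disables early stopping.
#' @return an \code{nts_train_config} list.
#' @export
train_config <- function(epochs = 300L, learning_rate = 1e-3, batch = Inf,
                         dt = 25L, stride = dt, beta = 0.05, gamma = 1.0,
                         seed = 0L, patience = Inf) {
  stopifnot(epochs >= 1, beta >= 0, gamma >= 0, dt >= 1, stride >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch = batch, dt = as.integer(dt), stride = as.integer(stride),
                 beta = beta, gamma = gamma, seed = as.integer(seed),
                 patience = patience),
            class = "nts_train_config")
}

# Forward pass + loss for one batch of windows, on tape. Returns the scalar
# loss node, the term breakdown (numeric), and the per-position merged /
# adjacency values needed by impute().
.loss_forward <- function(theta, cfg, data, beta, gamma, noise) {
  tape <- ad_tape()
  P <- .make_P(tape, theta)
  fwd <- .ad_run_direction(tape, P, "f", cfg, data, noise)
  bwd <- .ad_run_direction(tape, P, "b", cfg, data, noise)
  dt <- data$dt
  y_final <- .ad_merge(tape, P, cfg, fwd, bwd, dt)

  xlab <- do.call(rbind, data$X)
  mlab <- do.call(rbind, data$M)
  fden <- 1 / max(data$fcount, 1)
  mae_term <- function(pred) {
    ad_scale(ad_masked_abs_sum(pred, xlab, mlab), fden)
  }
  stack_field <- function(run, field) {
    ad_rbind(lapply(seq_len(dt), function(p) run$states[[p]][[field]]))
  }
  final_mae <- mae_term(y_final)
  s1f <- mae_term(stack_field(fwd, "Y1")); s1b <- mae_term(stack_field(bwd, "Y1"))
  s3f <- mae_term(stack_field(fwd, "Y2")); s3b <- mae_term(stack_field(bwd, "Y2"))

  link_term <- function(run) {
    acc <- NULL
    for (p in seq_len(dt)) {
      ssq <- ad_masked_sq_sum(run$states[[p]]$A_out, data$Aobs[[p]],
                              data$Amask[[p]])
      acc <- if (is.null(acc)) ssq else ad_add(acc, ssq)
    }
    ad_sqrt(ad_scale(acc, 1 / max(data$ecount, 1)))
  }
  lf <- link_term(fwd); lb <- link_term(bwd)

  kl_term <- function(lat) {
    ad_scale(ad_kl_sum(lat$mean, lat$log_variance), 1 / length(lat$mean$val))
  }
  klf <- kl_term(fwd$latent); klb <- kl_term(bwd$latent)

  total <- ad_add(final_mae,
           ad_add(ad_scale(ad_add(klf, klb), beta),
           ad_add(ad_add(s1f, s1b),
           ad_add(ad_scale(ad_add(lf, lb), gamma),
                  ad_add(s3f, s3b)))))
  breakdown <- list(final_mae = final_mae$val, kl_f = klf$val, kl_b = klb$val,
                    stage1_mae_f = s1f$val, stage1_mae_b = s1b$val,
                    link_frob_f = lf$val, link_frob_b = lb$val,
                    stage3_mae_f = s3f$val, stage3_mae_b = s3b$val,
                    beta = beta, gamma = gamma, total = total$val)
  list(tape = tape, total = total, breakdown = breakdown,
       y_final = y_final$val,
       a_f = lapply(seq_len(dt), function(p) fwd$states[[p]]$A_out$val),
       a_b = lapply(seq_len(dt), function(p) bwd$states[[p]]$A_out$val))
}

.adam_init <- function(theta) {
  list(m = lapply(theta, function(v) v * 0),
       v = lapply(theta, function(v) v * 0), t = 0L)
}

.adam_step <- function(theta, grads, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    theta[[nm]] <- theta[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(theta = theta, state = state)
}

#' Train the bidirectional VAE on a partially observed bundle
#'
#' Position embeddings are computed once from the observed graphs, the bundle
#' is cut into sliding windows, and the nine-term loss of
#' \code{\link{compute_loss}} is minimized with Adam. All randomness (weight
#' initialization, initial decoder memory, reparameterization noise) is
#' seeded, so identical calls reproduce identical loss trajectories.
#'
#' @param bundle an \code{nts_bundle}.
#' @param model_cfg a \code{\link{model_config}}.
#' @param train_cfg a \code{\link{train_config}}.
#' @param validation optional list(\code{features}, \code{mask}) of held-out
#'   entries (truth values and a binary mask disjoint from the observation
#'   mask); enables best-checkpoint tracking and early stopping.
#' @param verbose print per-epoch totals every 50 epochs.
#' @return an \code{nts_fit}: trained \code{model}, per-epoch \code{log}
#'   (one row of loss terms per epoch), \code{anchors}, and the configs.
#' @export
nts_train <- function(bundle, model_cfg = model_config(),
                      train_cfg = train_config(), validation = NULL,
                      verbose = FALSE) {
  .stop_if_invalid(bundle, "training bundle")
  d <- unname(nts_dim(bundle))
  anchors <- select_anchors(bundle, L = model_cfg$anchor_count,
                            strategy = "degree_top")
  positions <- build_position_tensor(bundle, anchors, c = model_cfg$restart)
  windows <- make_windows(bundle, train_cfg$dt, train_cfg$stride)
  if (length(windows) == 0) stop("no windows: dt larger than T")
  model <- init_model_params(model_cfg, n_features = unname(d[3]),
                             n_anchors = length(anchors$anchor_indices),
                             t_ref = unname(d[1]))
  bsz <- if (is.finite(train_cfg$batch)) max(1L, as.integer(train_cfg$batch))
         else length(windows)
  groups <- split(seq_along(windows), ceiling(seq_along(windows) / bsz))
  batches <- lapply(groups, function(idx) {
    .prepare_batch(windows[idx], .positions_for_windows(windows[idx], positions),
                   bundle$undirected)
  })
  starts <- lapply(groups, function(idx)
    vapply(windows[idx], function(w) w$start, 0L))

  theta <- model$theta
  adam <- .adam_init(theta)
  log_rows <- vector("list", train_cfg$epochs)
  best <- list(theta = theta, val = Inf, epoch = 0L)
  stale <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    terms_acc <- NULL
    val_pred <- if (!is.null(validation))
      list(sum = array(0, d), cnt = array(0, d)) else NULL
    for (gi in seq_along(batches)) {
      data <- batches[[gi]]
      noise <- .draw_noise((train_cfg$seed * 1009L + epoch * 131L + gi) %%
                             .Machine$integer.max,
                           data$WN, model_cfg$hidden_dim, model_cfg$latent_dim)
      fw <- .loss_forward(theta, model_cfg, data, train_cfg$beta,
                          train_cfg$gamma, noise)
      if (!is.finite(fw$breakdown$total))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      ad_backward(fw$tape, fw$total)
      grads <- lapply(stats::setNames(nm = names(fw$tape$params)),
                      function(nm) ad_grad(fw$tape, nm))
      upd <- .adam_step(theta, grads, adam, train_cfg$learning_rate)
      theta <- upd$theta; adam <- upd$state
      terms_acc <- if (is.null(terms_acc)) fw$breakdown else
        Map(`+`, terms_acc, fw$breakdown)
      if (!is.null(val_pred)) {
        for (wi in seq_along(starts[[gi]])) {
          rows <- (wi - 1L) * data$N + seq_len(data$N)
          for (p in seq_len(data$dt)) {
            g <- starts[[gi]][wi] + p
            y <- fw$y_final[(p - 1L) * data$WN + rows, , drop = FALSE]
            val_pred$sum[g, , ] <- val_pred$sum[g, , ] + y
            val_pred$cnt[g, , ] <- val_pred$cnt[g, , ] + 1
          }
        }
      }
    }
    terms <- lapply(terms_acc, function(v) v / length(batches))
    log_rows[[epoch]] <- data.frame(epoch = epoch, as.data.frame(terms))
    if (!is.null(validation)) {
      pred <- val_pred$sum / pmax(val_pred$cnt, 1)
      vmae <- masked_mae(pred, validation$features, validation$mask)
      if (vmae < best$val) {
        best <- list(theta = theta, val = vmae, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= train_cfg$patience) {
          log_rows <- log_rows[seq_len(epoch)]
          break
        }
      }
    }
    if (verbose && epoch %% 50L == 0L)
      message(sprintf("epoch %d total %.4f", epoch, terms$total))
  }
  model$theta <- if (!is.null(validation) && is.finite(best$val))
    best$theta else theta
  structure(list(model = model, log = do.call(rbind, log_rows),
                 anchors = anchors, train_config = train_cfg,
                 best_epoch = if (!is.null(validation)) best$epoch else NA),
            class = "nts_fit")
}

#' Impute a bundle with a trained model
#'
#' Runs the bidirectional model over windows covering the whole sequence (an
#' extra window anchored at the end is added when the stride leaves a tail
#' uncovered). At observed entries the output equals the input exactly; at
#' missing entries the merged feature prediction and the average of the two
#' directions' predicted adjacencies are inserted, averaging arithmetically
#' over overlapping windows. The adjacency output is symmetric for
#' undirected bundles with a zero diagonal.
#'
#' @param bundle an \code{nts_bundle} dimensioned like the training data
#'   (same \code{D}; \code{N} must match the anchor set).
#' @param fit an \code{nts_fit} from \code{\link{nts_train}}.
#' @param dt,stride window geometry (default: the fit's training values).
#' @return an \code{nts_imputation}: \code{features} (\code{T x N x D}),
#'   \code{adjacency} (\code{T x N x N}), and binary provenance arrays
#'   \code{imputed_features}, \code{imputed_edges} marking filled entries.
#' @export
nts_impute <- function(bundle, fit, dt = NULL, stride = NULL) {
  d <- unname(nts_dim(bundle))
  model <- fit$model
  if (unname(d[3]) != model$n_features)
    stop("bundle feature dimension disagrees with the trained model")
  if (any(fit$anchors$anchor_indices > d[2]))
    stop("bundle node count disagrees with the trained anchor set")
  if (is.null(dt)) dt <- min(fit$train_config$dt, unname(d[1]))
  if (is.null(stride)) stride <- min(fit$train_config$stride, dt)
  positions <- build_position_tensor(bundle, fit$anchors,
                                     c = model$config$restart)
  windows <- make_windows(bundle, dt, stride)
  last_end <- windows[[length(windows)]]$start + dt
  if (last_end < d[1])
    windows <- c(windows, list(window_slice(bundle, unname(d[1]) - dt, dt)))

  data <- .prepare_batch(windows, .positions_for_windows(windows, positions),
                         bundle$undirected)
  noise <- .draw_noise(fit$train_config$seed, data$WN,
                       model$config$hidden_dim, model$config$latent_dim)
  fw <- .loss_forward(model$theta, model$config, data,
                      fit$train_config$beta, fit$train_config$gamma, noise)

  fsum <- array(0, d); fcnt <- array(0, d)
  asum <- array(0, c(d[1], d[2], d[2])); acnt <- array(0, c(d[1], d[2], d[2]))
  for (wi in seq_along(windows)) {
    rows <- (wi - 1L) * data$N + seq_len(data$N)
    for (p in seq_len(dt)) {
      g <- windows[[wi]]$start + p
      fsum[g, , ] <- fsum[g, , ] +
        fw$y_final[(p - 1L) * data$WN + rows, , drop = FALSE]
      fcnt[g, , ] <- fcnt[g, , ] + 1
      ap <- 0.5 * (fw$a_f[[p]][rows, rows] + fw$a_b[[p]][rows, rows])
      asum[g, , ] <- asum[g, , ] + ap
      acnt[g, , ] <- acnt[g, , ] + 1
    }
  }
  ffill <- fsum / pmax(fcnt, 1)
  afill <- asum / pmax(acnt, 1)

  features <- ffill
  obs <- bundle$feature_mask == 1
  features[obs] <- bundle$features[obs]
  adjacency <- afill
  eobs <- bundle$edge_mask == 1
  adjacency[eobs] <- bundle$adjacency[eobs]
  adjacency[!is.finite(adjacency)] <- 0
  for (t in seq_len(d[1])) diag(adjacency[t, , ]) <- 0
  structure(list(features = features, adjacency = adjacency,
                 imputed_features = 1 - bundle$feature_mask,
                 imputed_edges = 1 - bundle$edge_mask),
            class = "nts_imputation")
}
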