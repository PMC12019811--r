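#' Model configuration
#'
#' Hyperparameters of the bidirectional VAE. The two directions (forward and
#' backward in time) carry fully separate parameter sets; a merge network
#' combines their per-step representations into the final imputation.
#'
#' @param hidden_dim recurrent/graph hidden width \code{d_h}.
#' @param latent_dim latent width \code{d_z} of the variational posterior.
#' @param time_pairs number \code{k} of learnable cos/sin frequency pairs in
#'   the Bochner time encoding (the encoding is a unit-norm \code{2k}-vector).
#' @param heads self-attention heads in the third decoder stage.
#' @param mlp_hidden hidden width of every two-layer MLP.
#' @param restart RWR restart probability used for position embeddings.
#' @param anchor_count number of anchor nodes \code{L}; \code{NULL} selects
#'   \code{min(N, ceiling(log2(N))^2)}.
#' @param seed integer seed fixed before any parameter initialization.
#' @return a \code{nts_model_config} list.
#' @export
model_config <- function(hidden_dim = 64L, latent_dim = 32L, time_pairs = 8L,
                         heads = 2L, mlp_hidden = 64L, restart = 0.15,
                         anchor_count = NULL, seed = 0L) {
  stopifnot(hidden_dim >= 1, latent_dim >= 1, time_pairs >= 1,
            heads >= 1, mlp_hidden >= 1, restart > 0, restart <= 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 latent_dim = as.integer(latent_dim),
                 time_pairs = as.integer(time_pairs),
                 heads = as.integer(heads),
                 mlp_hidden = as.integer(mlp_hidden),
                 restart = restart,
                 anchor_count = anchor_count,
                 head_dim = max(2L, as.integer(hidden_dim) %/% as.integer(heads)),
                 seed = as.integer(seed)),
            class = "nts_model_config")
}

.glorot <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

#' Initialize model parameters
#'
#' Creates the full parameter set: a forward and a backward replica of the
#' encoder/decoder plus the bidirectional merge MLP. Weights are
#' Glorot-uniform, biases zero, and the time-encoding frequencies are
#' log-spaced over \code{[1/t_ref, 1]} cycles so the initial encoding resolves
#' periods from one step up to the typical sequence length. Deterministic
#' given \code{config$seed}.
#'
#' @param config a \code{\link{model_config}}.
#' @param n_features number of node features \code{D}.
#' @param n_anchors number of anchors \code{L} (width of position scores).
#' @param t_ref reference sequence length for frequency initialization.
#' @return object of class \code{nts_model}: \code{config}, \code{theta}
#'   (flat named list of numeric matrices/vectors), dimension record.
#' @export
init_model_params <- function(config, n_features, n_anchors, t_ref = 100) {
  dh <- config$hidden_dim; dz <- config$latent_dim; k <- config$time_pairs
  mh <- config$mlp_hidden; dk <- config$head_dim; D <- n_features
  L <- n_anchors
  theta <- list()
  .with_seed(config$seed, {
    for (dir in c("f", "b")) {
      p <- function(name, val) theta[[paste0(dir, ".", name)]] <<- val
      enc_in <- 2 * D + L
      p("enc1.Wx", .glorot(enc_in, 3 * dh)); p("enc1.Wh", .glorot(dh, 3 * dh))
      p("enc1.bx", numeric(3 * dh)); p("enc1.bh", numeric(3 * dh))
      p("enc2.Wx", .glorot(dh, 3 * dh)); p("enc2.Wh", .glorot(dh, 3 * dh))
      p("enc2.bx", numeric(3 * dh)); p("enc2.bh", numeric(3 * dh))
      p("enc.Wmu", .glorot(dh, dz)); p("enc.bmu", numeric(dz))
      p("enc.Wlv", .glorot(dh, dz)); p("enc.blv", numeric(dz))
      p("dec.W1", .glorot(dh, D)); p("dec.b1", numeric(D))
      p("dec.Wu", .glorot(2 * D + L + dh, dh)); p("dec.bu", numeric(dh))
      p("time.w", matrix(2 * pi * exp(seq(log(1 / max(t_ref, 2)), log(1),
                                          length.out = k)), 1, k))
      p("link.W1", .glorot(4 * dh + 2 * k, mh)); p("link.b1", numeric(mh))
      p("link.W2", .glorot(mh, 1)); p("link.b2", numeric(1))
      p("prop.W1", .glorot(dh, dh)); p("prop.W2", .glorot(dh, dh))
      p("prop.b", numeric(dh))
      cw <- dz + 2 * dh + 2 * D
      for (h in seq_len(config$heads)) {
        p(sprintf("attn.Wq%d", h), .glorot(cw, dk))
        p(sprintf("attn.Wk%d", h), .glorot(cw, dk))
        p(sprintf("attn.Wv%d", h), .glorot(cw, dk))
      }
      p("attn.W1", .glorot(config$heads * dk, mh)); p("attn.b1", numeric(mh))
      p("attn.W2", .glorot(mh, dh)); p("attn.b2", numeric(dh))
      p("y2.W1", .glorot(3 * dh, mh)); p("y2.b1", numeric(mh))
      p("y2.W2", .glorot(mh, D)); p("y2.b2", numeric(D))
      p("mem.Wx", .glorot(dz + 2 * D + dh, 3 * dh))
      p("mem.Wh", .glorot(dh, 3 * dh))
      p("mem.bx", numeric(3 * dh)); p("mem.bh", numeric(3 * dh))
    }
    theta[["m.W1"]] <- .glorot(6 * dh, mh); theta[["m.b1"]] <- numeric(mh)
    theta[["m.W2"]] <- .glorot(mh, D); theta[["m.b2"]] <- numeric(D)
  })
  structure(list(config = config, theta = theta,
                 n_features = D, n_anchors = L, format = "nts-model-v1"),
            class = "nts_model")
}

#' Bochner time encoding
#'
#' Unit-norm vector of learnable Fourier features
#' \code{(1/sqrt(k)) * [cos(w1 t), sin(w1 t), ..., cos(wk t), sin(wk t)]}.
#' Because \code{cos(w * (a t)) = cos((a w) * t)}, the encoding is invariant
#' to rescaling time if the frequencies rescale inversely, and it is defined
#' for any (also future, unseen) timestamp.
#'
#' @param t scalar timestamp.
#' @param w numeric vector of \code{k} frequencies.
#' @return numeric vector of length \code{2k} with Euclidean norm 1.
#' @export
time_encoding <- function(t, w) {
  k <- length(w)
  stopifnot(k >= 1)
  as.vector(rbind(cos(w * t), sin(w * t))) / sqrt(k)
}

#' Filler operator
#'
#' Elementwise blend \code{mask * x_obs + (1 - mask) * fill}: keeps observed
#' entries exactly and inserts the prediction elsewhere. Values of
#' \code{x_obs} at masked-out entries (which may be \code{NA}) never reach
#' the output.
#'
#' @param x_obs,mask,fill equally shaped numeric arrays; \code{mask} binary.
#' @return array of the common shape.
#' @export
apply_filler <- function(x_obs, mask, fill) {
  if (!.same_shape(x_obs, mask) || !.same_shape(x_obs, fill))
    stop("apply_filler: shapes of x_obs, mask and fill must match")
  out <- fill
  keep <- mask == 1
  out[keep] <- x_obs[keep]
  out
}

## ---- internal tape-level building blocks ----------------------------------

# Parameter-node accessor with caching, so each tensor becomes one tape leaf.
.make_P <- function(tape, theta) {
  cache <- new.env(parent = emptyenv())
  function(name) {
    nd <- cache[[name]]
    if (is.null(nd)) {
      v <- theta[[name]]
      if (is.null(v)) stop("unknown parameter: ", name)
      nd <- ad_param(tape, v, name)
      cache[[name]] <- nd
    }
    nd
  }
}

.ad_linear <- function(x, W, b) ad_affine(x, W, b)

# GRU cell through the fused tape op; x may be a node or a constant matrix.
.ad_gru_cell <- function(x, h, P, prefix, dh) {
  ad_gru(x, h, P(paste0(prefix, ".Wx")), P(paste0(prefix, ".Wh")),
         P(paste0(prefix, ".bx")), P(paste0(prefix, ".bh")), dh)
}

# Batched Bochner encoding for the W window timestamps at one step:
# returns list(nodes = WN x 2k, pairs = P x 2k), interleaved cos/sin columns.
.ad_time_code <- function(tape, tvec, P, dir, k, Erow, Epair) {
  code <- ad_timecode(P(paste0(dir, ".time.w")), tvec, k)
  list(nodes = ad_lmm(tape, Erow, code), pairs = ad_lmm(tape, Epair, code))
}

# Second-stage link prediction: score all within-window ordered node pairs
# with a two-layer MLP, softplus to nonnegative weights, scatter into the
# block adjacency, zero diagonal (pairs exclude it), symmetrize if undirected.
.ad_link <- function(U, H, tpair, P, dir, geo) {
  feat <- ad_paircat(U, H, tpair, geo$pair_i, geo$pair_j)
  hid <- ad_relu(.ad_linear(feat, P(paste0(dir, ".link.W1")),
                            P(paste0(dir, ".link.b1"))))
  sc <- ad_softplus(.ad_linear(hid, P(paste0(dir, ".link.W2")),
                               P(paste0(dir, ".link.b2"))))
  ad_scatter_sym(sc, geo$pair_i, geo$pair_j, geo$WN, geo$undirected)
}

# One round of degree-normalized message passing on the predicted graph:
# H_graph = relu(D^-1 A U W1 + U W2 + b), weighted degree clamped at 1.
.ad_prop <- function(U, A, P, dir) {
  ad_prop_fused(U, A, P(paste0(dir, ".prop.W1")), P(paste0(dir, ".prop.W2")),
                P(paste0(dir, ".prop.b")))
}

# Scaled dot-product self-attention over nodes (block-diagonal across
# windows) followed by a two-layer MLP.
.ad_attn <- function(C, P, dir, cfg, addmask) {
  heads <- lapply(seq_len(cfg$heads), function(h) {
    ad_attn_head(C, P(sprintf("%s.attn.Wq%d", dir, h)),
                 P(sprintf("%s.attn.Wk%d", dir, h)),
                 P(sprintf("%s.attn.Wv%d", dir, h)),
                 1 / sqrt(cfg$head_dim), addmask)
  })
  cat <- if (length(heads) > 1) ad_cbind(heads) else heads[[1]]
  hid <- ad_relu(.ad_linear(cat, P(paste0(dir, ".attn.W1")),
                            P(paste0(dir, ".attn.b1"))))
  .ad_linear(hid, P(paste0(dir, ".attn.W2")), P(paste0(dir, ".attn.b2")))
}

# Full decoder step on tape. `cn` holds the step's constant matrices
# (xclean, m, omm, r) and `tc` the time-code nodes.
.ad_decode_step <- function(tape, P, dir, cfg, geo, cn, tc, z, H) {
  Y1 <- .ad_linear(H, P(paste0(dir, ".dec.W1")), P(paste0(dir, ".dec.b1")))
  O <- ad_fill(Y1, cn$xclean, cn$omm)
  U <- .ad_linear(ad_catx(tape, list(O, cn$m, cn$r, H)),
                  P(paste0(dir, ".dec.Wu")), P(paste0(dir, ".dec.bu")))
  A <- .ad_link(U, H, tc$pairs, P, dir, geo)
  Hg <- .ad_prop(U, A, P, dir)
  C <- ad_catx(tape, list(z, H, Hg, O, cn$m))
  Hout <- .ad_attn(C, P, dir, cfg, geo$attn_addmask)
  y2h <- ad_relu(.ad_linear(ad_catx(tape, list(Hout, H, Hg)),
                            P(paste0(dir, ".y2.W1")), P(paste0(dir, ".y2.b1"))))
  Y2 <- .ad_linear(y2h, P(paste0(dir, ".y2.W2")), P(paste0(dir, ".y2.b2")))
  Xout <- ad_fill(Y2, cn$xclean, cn$omm)
  Hnew <- .ad_gru_cell(ad_catx(tape, list(z, Xout, cn$m, Hg)), H, P,
                       paste0(dir, ".mem"), cfg$hidden_dim)
  list(H_prev = H, Y1 = Y1, O = O, U = U, A_out = A, H_graph = Hg,
       H_out = Hout, Y2 = Y2, X_out = Xout, H = Hnew)
}

# Encoder on tape: 2-layer GRU over the window in the given direction,
# linear heads to posterior mean / log-variance, reparameterized sample.
.ad_encode <- function(tape, P, dir, cfg, data, order, eta) {
  dh <- cfg$hidden_dim
  h1 <- ad_const(tape, matrix(0, data$WN, dh))
  h2 <- ad_const(tape, matrix(0, data$WN, dh))
  for (p in order) {
    h1 <- .ad_gru_cell(data$ENC[[p]], h1, P, paste0(dir, ".enc1"), dh)
    h2 <- .ad_gru_cell(h1, h2, P, paste0(dir, ".enc2"), dh)
  }
  mu <- .ad_linear(h2, P(paste0(dir, ".enc.Wmu")), P(paste0(dir, ".enc.bmu")))
  lv <- .ad_linear(h2, P(paste0(dir, ".enc.Wlv")), P(paste0(dir, ".enc.blv")))
  z <- ad_add(mu, ad_mul(ad_exp(ad_scale(lv, 0.5)), ad_const(tape, eta)))
  list(mean = mu, log_variance = lv, sample = z)
}

# One direction end to end: encode, then unroll the decoder over the window.
# States are stored by window position (1..dt) whatever the direction, so the
# merge step never needs re-indexing.
.ad_run_direction <- function(tape, P, dir, cfg, data, noise) {
  dt <- data$dt
  order <- if (dir == "f") seq_len(dt) else rev(seq_len(dt))
  latent <- .ad_encode(tape, P, dir, cfg, data, order, noise$eta)
  H <- ad_const(tape, noise$h0)
  states <- vector("list", dt)
  for (p in order) {
    cn <- list(xclean = data$X[[p]], m = data$M[[p]],
               omm = data$OMM[[p]], r = data$R[[p]])
    tc <- .ad_time_code(tape, data$TS[[p]], P, dir, cfg$time_pairs,
                        data$Erow, data$Epair)
    st <- .ad_decode_step(tape, P, dir, cfg, data$geo, cn, tc,
                          latent$sample, H)
    H <- st$H
    states[[p]] <- st
  }
  list(latent = latent, states = states, order = order)
}

# Bidirectional merge MLP over stacked per-step representations.
.ad_merge <- function(tape, P, cfg, fwd, bwd, dt) {
  rows <- lapply(seq_len(dt), function(p) {
    ad_cbind(list(fwd$states[[p]]$H_out, bwd$states[[p]]$H_out,
                  fwd$states[[p]]$H_graph, bwd$states[[p]]$H_graph,
                  fwd$states[[p]]$H, bwd$states[[p]]$H))
  })
  stacked <- ad_rbind(rows)
  hid <- ad_relu(.ad_linear(stacked, P("m.W1"), P("m.b1")))
  .ad_linear(hid, P("m.W2"), P("m.b2"))   # (dt*WN) x D
}

## ---- batch preparation -----------------------------------------------------

# Stack a list of equal-length windows into per-position constants; windows
# occupy disjoint row blocks of size N, and all pair/attention structure is
# block-diagonal so windows never interact.
.prepare_batch <- function(windows, positions_list, undirected) {
  W <- length(windows)
  d <- nts_dim(windows[[1]])
  dt <- unname(d[1]); N <- unname(d[2]); D <- unname(d[3])
  L <- dim(positions_list[[1]]$scores)[3]
  WN <- W * N
  X <- M <- OMM <- R <- TS <- Aobs <- Amask <- vector("list", dt)
  for (p in seq_len(dt)) {
    X[[p]] <- matrix(0, WN, D); M[[p]] <- matrix(0, WN, D)
    R[[p]] <- matrix(0, WN, L); TS[[p]] <- matrix(0, W, 1)
    Aobs[[p]] <- matrix(0, WN, WN); Amask[[p]] <- matrix(0, WN, WN)
  }
  for (w in seq_len(W)) {
    win <- windows[[w]]
    rows <- (w - 1L) * N + seq_len(N)
    xc <- .clean_features(win)
    for (p in seq_len(dt)) {
      X[[p]][rows, ] <- matrix(xc[p, , ], N, D)
      M[[p]][rows, ] <- matrix(win$feature_mask[p, , ], N, D)
      R[[p]][rows, ] <- matrix(positions_list[[w]]$scores[p, , ], N, L)
      TS[[p]][w, 1] <- win$timestamps[p]
      at <- win$adjacency[p, , ]; mt <- win$edge_mask[p, , ]
      at[mt == 0 | !is.finite(at)] <- 0
      Aobs[[p]][rows, rows] <- at
      mt_off <- mt; diag(mt_off) <- 0
      Amask[[p]][rows, rows] <- mt_off
    }
  }
  for (p in seq_len(dt)) OMM[[p]] <- 1 - M[[p]]
  ENC <- lapply(seq_len(dt), function(p) cbind(X[[p]], M[[p]], R[[p]]))
  block <- matrix(0, WN, WN)
  for (w in seq_len(W)) {
    rows <- (w - 1L) * N + seq_len(N)
    block[rows, rows] <- 1
  }
  pair_i <- integer(0); pair_j <- integer(0)
  for (w in seq_len(W)) {
    off <- (w - 1L) * N
    grid <- expand.grid(i = seq_len(N), j = seq_len(N))
    grid <- grid[grid$i != grid$j, ]
    pair_i <- c(pair_i, off + grid$i)
    pair_j <- c(pair_j, off + grid$j)
  }
  Erow <- matrix(0, WN, W)
  for (w in seq_len(W)) Erow[(w - 1L) * N + seq_len(N), w] <- 1
  Epair <- matrix(0, length(pair_i), W)
  for (q in seq_along(pair_i)) Epair[q, (pair_i[q] - 1L) %/% N + 1L] <- 1
  geo <- list(WN = WN, pair_i = pair_i, pair_j = pair_j,
              undirected = undirected,
              attn_addmask = (block - 1) * 1e30)
  list(W = W, N = N, D = D, L = L, dt = dt, WN = WN,
       X = X, M = M, OMM = OMM, R = R, TS = TS, ENC = ENC,
       Aobs = Aobs, Amask = Amask, Erow = Erow, Epair = Epair,
       geo = geo,
       fcount = sum(vapply(M, sum, 0)),
       ecount = sum(vapply(Amask, sum, 0)))
}

# Noise shared by both directions of a run: the initial decoder memory
# H0 ~ N(0, 1/d_h) and the reparameterization draw. Using one seed for both
# directions makes the time-reversal symmetry of the architecture exact.
.draw_noise <- function(seed, WN, dh, dz) {
  .with_seed(seed, list(
    h0 = matrix(stats::rnorm(WN * dh, sd = 1 / sqrt(dh)), WN, dh),
    eta = matrix(stats::rnorm(WN * dz), WN, dz)))
}

.positions_for_windows <- function(windows, positions) {
  lapply(windows, function(w) {
    start <- if (is.null(w$start)) 0L else w$start
    idx <- start + seq_len(nts_dim(w)[1])
    list(scores = positions$scores[idx, , , drop = FALSE])
  })
}

## ---- exported single-window / single-step wrappers -------------------------

#' Encode a window into the variational posterior
#'
#' Runs the 2-layer recurrent encoder over the window (features, masks and
#' position embeddings concatenated per node per step) and returns the
#' diagonal-Gaussian posterior and a seeded reparameterized sample.
#'
#' @param window an \code{nts_window}.
#' @param positions an \code{nts_positions} for the full parent bundle (or
#'   the window itself if \code{window$start} is 0).
#' @param model an \code{nts_model}.
#' @param direction \code{"f"} (forward time) or \code{"b"} (reversed).
#' @param seed seed for the reparameterization draw.
#' @return list with matrices \code{mean}, \code{log_variance},
#'   \code{sample}, each \code{N x latent_dim}.
#' @export
nts_encode <- function(window, positions, model, direction = c("f", "b"),
                       seed = 0L) {
  direction <- match.arg(direction)
  if (any(!is.finite(window$features[window$feature_mask == 1])))
    stop("non-finite feature values at observed entries")
  tape <- ad_tape()
  P <- .make_P(tape, model$theta)
  data <- .prepare_batch(list(window),
                         .positions_for_windows(list(window), positions),
                         window$undirected)
  cfg <- model$config
  noise <- .draw_noise(seed, data$WN, cfg$hidden_dim, cfg$latent_dim)
  dt <- data$dt
  order <- if (direction == "f") seq_len(dt) else rev(seq_len(dt))
  lat <- .ad_encode(tape, P, direction, cfg, data, order, noise$eta)
  list(mean = lat$mean$val, log_variance = lat$log_variance$val,
       sample = lat$sample$val)
}

#' Predict the weighted adjacency from node embeddings
#'
#' Scores every ordered node pair with a two-layer MLP on
#' \code{[U_i, U_j, H_i, H_j, f(t)]}, maps scores through softplus so
#' weights are nonnegative, zeroes the diagonal, and symmetrizes as
#' \code{(A + t(A)) / 2} when \code{undirected}.
#'
#' @param U_t \code{N x d_h} node embeddings of the current step.
#' @param H_prev \code{N x d_h} previous hidden state.
#' @param tcode time-encoding vector of length \code{2k}.
#' @param model an \code{nts_model}.
#' @param direction \code{"f"} or \code{"b"}.
#' @param undirected symmetrize the output.
#' @return nonnegative \code{N x N} matrix with zero diagonal.
#' @export
predict_links <- function(U_t, H_prev, tcode, model, direction = c("f", "b"),
                          undirected = TRUE) {
  direction <- match.arg(direction)
  n <- nrow(U_t)
  tape <- ad_tape()
  P <- .make_P(tape, model$theta)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  grid <- grid[grid$i != grid$j, ]
  geo <- list(WN = n, pair_i = grid$i, pair_j = grid$j, undirected = undirected)
  tpair <- ad_const(tape, matrix(rep(tcode, each = nrow(grid)), nrow(grid)))
  .ad_link(ad_const(tape, U_t), ad_const(tape, H_prev), tpair, P,
           direction, geo)$val
}

#' Propagate node embeddings over a predicted graph
#'
#' One round of degree-normalized weighted message passing
#' \code{relu(D^-1 A U W1 + U W2 + b)} with the weighted degree clamped at 1
#' (so empty neighborhoods contribute nothing rather than dividing by zero).
#' The operation is permutation-equivariant.
#'
#' @param U_t \code{N x d_h} node embeddings.
#' @param A_t nonnegative \code{N x N} adjacency.
#' @param model an \code{nts_model}.
#' @param direction \code{"f"} or \code{"b"}.
#' @return \code{N x d_h} matrix.
#' @export
propagate_graph <- function(U_t, A_t, model, direction = c("f", "b")) {
  direction <- match.arg(direction)
  tape <- ad_tape()
  P <- .make_P(tape, model$theta)
  .ad_prop(ad_const(tape, U_t), ad_const(tape, A_t), P, direction)$val
}

#' One decoder step
#'
#' Executes the three prediction stages for a single time step: (1) linear
#' initial fill from the previous hidden state plus the filler operator;
#' (2) link prediction on the embeddings \code{U_t} followed by message
#' passing on the predicted graph; (3) self-attention over nodes on
#' \code{[z, H_prev, H_graph, O_t, M_t]}, an MLP head for the refined
#' prediction, the filler again, and finally the gated recurrent memory
#' update.
#'
#' @param x_obs_t \code{N x D} observed features (NA allowed where masked).
#' @param mask_t \code{N x D} binary mask.
#' @param R_t \code{N x L} position scores at this step.
#' @param z \code{N x latent_dim} latent sample.
#' @param H_prev \code{N x d_h} previous hidden state.
#' @param t scalar timestamp.
#' @param model an \code{nts_model}.
#' @param direction \code{"f"} or \code{"b"}.
#' @param undirected symmetrize predicted adjacency.
#' @return list of numeric matrices: \code{H_prev}, \code{Y1}, \code{O},
#'   \code{U}, \code{A_out}, \code{H_graph}, \code{H_out}, \code{Y2},
#'   \code{X_out}, \code{H}.
#' @export
decode_step <- function(x_obs_t, mask_t, R_t, z, H_prev, t, model,
                        direction = c("f", "b"), undirected = TRUE) {
  direction <- match.arg(direction)
  n <- nrow(mask_t)
  xclean <- x_obs_t
  xclean[mask_t == 0 | !is.finite(xclean)] <- 0
  if (any(!is.finite(x_obs_t[mask_t == 1])))
    stop("non-finite feature values at observed entries")
  tape <- ad_tape()
  P <- .make_P(tape, model$theta)
  cfg <- model$config
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  grid <- grid[grid$i != grid$j, ]
  geo <- list(WN = n, pair_i = grid$i, pair_j = grid$j,
              undirected = undirected,
              attn_addmask = matrix(0, n, n))
  cn <- list(xclean = xclean, m = mask_t, omm = 1 - mask_t, r = R_t)
  k <- cfg$time_pairs
  tc <- .ad_time_code(tape, matrix(t, 1, 1), P, direction, k,
                      matrix(1, n, 1), matrix(1, nrow(grid), 1))
  st <- .ad_decode_step(tape, P, direction, cfg, geo, cn, tc,
                        ad_const(tape, z), ad_const(tape, H_prev))
  out <- lapply(st, function(e) e$val)
  for (nm in names(out)) {
    if (any(!is.finite(out[[nm]])))
      stop("non-finite values in decoder stage output '", nm, "'")
  }
  out
}

#' Run one direction of the VAE over a window
#'
#' Encodes the window, then unrolls the decoder over all steps in the stated
#' direction (the backward direction processes the time-reversed window with
#' its own parameter set). Both directions of a given seed share the initial
#' memory draw and the reparameterization noise.
#'
#' @param window an \code{nts_window}.
#' @param positions an \code{nts_positions} of the parent bundle.
#' @param model an \code{nts_model}.
#' @param direction \code{"f"} or \code{"b"}.
#' @param seed noise seed.
#' @return list: \code{latent} (numeric posterior as in
#'   \code{\link{nts_encode}}), \code{states} (per-step numeric
#'   \code{decode_step} outputs, in processing order), \code{order} (window
#'   positions visited, 1-based).
#' @export
run_window <- function(window, positions, model, direction = c("f", "b"),
                       seed = 0L) {
  direction <- match.arg(direction)
  tape <- ad_tape()
  P <- .make_P(tape, model$theta)
  cfg <- model$config
  data <- .prepare_batch(list(window),
                         .positions_for_windows(list(window), positions),
                         window$undirected)
  noise <- .draw_noise(seed, data$WN, cfg$hidden_dim, cfg$latent_dim)
  run <- .ad_run_direction(tape, P, direction, cfg, data, noise)
  states_num <- lapply(run$order, function(p)
    lapply(run$states[[p]], function(e) e$val))
  list(latent = list(mean = run$latent$mean$val,
                     log_variance = run$latent$log_variance$val,
                     sample = run$latent$sample$val),
       states = states_num, order = run$order)
}

#' Merge forward and backward passes into the final imputation
#'
#' Re-aligns the backward states to forward time and applies the merge MLP to
#' \code{[H_out_f, H_out_b, H_graph_f, H_graph_b, H_f, H_b]} per step and
#' node.
#'
#' @param forward,backward outputs of \code{\link{run_window}} for the two
#'   directions of the same window.
#' @param model an \code{nts_model}.
#' @return numeric array \code{dt x N x D}.
#' @export
merge_bidirectional <- function(forward, backward, model) {
  dt <- length(forward$states)
  if (length(backward$states) != dt)
    stop("forward and backward passes cover different numbers of steps")
  by_pos <- function(run) {
    out <- vector("list", dt)
    for (i in seq_len(dt)) out[[run$order[i]]] <- run$states[[i]]
    out
  }
  fs <- by_pos(forward); bs <- by_pos(backward)
  tape <- ad_tape()
  P <- .make_P(tape, model$theta)
  rows <- lapply(seq_len(dt), function(p) {
    ad_const(tape, cbind(fs[[p]]$H_out, bs[[p]]$H_out,
                         fs[[p]]$H_graph, bs[[p]]$H_graph,
                         fs[[p]]$H, bs[[p]]$H))
  })
  stacked <- ad_rbind(rows)
  hid <- ad_relu(.ad_linear(stacked, P("m.W1"), P("m.b1")))
  y <- .ad_linear(hid, P("m.W2"), P("m.b2"))$val
  n <- nrow(fs[[1]]$H_out)
  D <- ncol(y)
  out <- array(0, c(dt, n, D))
  for (p in seq_len(dt)) out[p, , ] <- y[(p - 1L) * n + seq_len(n), , drop = FALSE]
  out
}
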