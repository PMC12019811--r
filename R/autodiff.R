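# Tape-based reverse-mode automatic differentiation over dense matrices.
#
# Every differentiable quantity is a node: an environment holding the forward
# value (`val`, a matrix or numeric vector for biases), the accumulated
# adjoint (`grad`), the parent nodes and a backward closure mapping the
# node's adjoint to a list of parent adjoints. Nodes are appended to a tape
# in creation order; the backward sweep walks the tape in reverse, so the
# topological order is the creation order (eager evaluation guarantees it).
# This is deliberately small: only the operations the model needs exist.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp$params <- list()
  tp
}

ad_node <- function(tape, val, parents = NULL, backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$tape <- tape
  n <- tape$n + 1L
  if (n > length(tape$nodes)) length(tape$nodes) <- 2L * n
  tape$nodes[[n]] <- e
  tape$n <- n
  e
}

ad_const <- function(tape, v) ad_node(tape, v)

# Parameter leaf; registered by name so gradients can be collected after the
# backward sweep.
ad_param <- function(tape, v, name) {
  e <- ad_node(tape, v)
  tape$params[[name]] <- e
  e
}

# Reverse sweep seeded with d(loss)/d(loss) = 1.
ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    e <- tape$nodes[[i]]
    g <- e$grad
    if (is.null(g) || is.null(e$backfn)) next
    gs <- e$backfn(g)
    ps <- e$parents
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
  }
  invisible(NULL)
}

ad_grad <- function(tape, name) {
  e <- tape$params[[name]]
  if (is.null(e$grad)) e$val * 0 else e$grad
}

## ---- arithmetic -----------------------------------------------------------

ad_mm <- function(a, b) {
  va <- a$val; vb <- b$val
  ad_node(a$tape, va %*% vb, list(a, b),
          function(g) list(g %*% t(vb), crossprod(va, g)))
}

ad_add <- function(a, b) {
  ad_node(a$tape, a$val + b$val, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(a$tape, a$val - b$val, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  va <- a$val; vb <- b$val
  ad_node(a$tape, va * vb, list(a, b), function(g) list(g * vb, g * va))
}

ad_scale <- function(a, s) {
  ad_node(a$tape, a$val * s, list(a), function(g) list(g * s))
}

# Add a bias vector across the rows of a matrix.
ad_addbias <- function(a, b) {
  vb <- b$val
  ad_node(a$tape, sweep(a$val, 2L, vb, "+"), list(a, b),
          function(g) list(g, colSums(g)))
}

# Multiply row i of `a` by s[i]; `s` is an n x 1 column node.
ad_rowscale <- function(a, s) {
  va <- a$val; sv <- as.vector(s$val)
  ad_node(a$tape, va * sv, list(a, s),
          function(g) list(g * sv, matrix(rowSums(g * va), ncol = 1L)))
}

## ---- elementwise nonlinearities -------------------------------------------

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(a$tape, s, list(a), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(a) {
  th <- tanh(a$val)
  ad_node(a$tape, th, list(a), function(g) list(g * (1 - th * th)))
}

ad_relu <- function(a) {
  v <- a$val
  pos <- v > 0
  ad_node(a$tape, v * pos, list(a), function(g) list(g * pos))
}

ad_softplus <- function(a) {
  v <- a$val
  out <- ifelse(v > 30, v, log1p(exp(pmin(v, 30))))
  sg <- 1 / (1 + exp(-v))
  ad_node(a$tape, out, list(a), function(g) list(g * sg))
}

ad_exp <- function(a) {
  ex <- exp(a$val)
  ad_node(a$tape, ex, list(a), function(g) list(g * ex))
}

ad_cos <- function(a) {
  v <- a$val
  ad_node(a$tape, cos(v), list(a), function(g) list(-g * sin(v)))
}

ad_sin <- function(a) {
  v <- a$val
  ad_node(a$tape, sin(v), list(a), function(g) list(g * cos(v)))
}

ad_abs <- function(a) {
  v <- a$val
  ad_node(a$tape, abs(v), list(a), function(g) list(g * sign(v)))
}

# Guarded square root: subgradient bounded near zero.
ad_sqrt <- function(a, eps = 1e-12) {
  s <- sqrt(pmax(a$val, 0))
  ad_node(a$tape, s, list(a), function(g) list(g / (2 * pmax(s, eps))))
}

ad_clampmin <- function(a, m) {
  v <- a$val
  keep <- v > m
  ad_node(a$tape, pmax(v, m), list(a), function(g) list(g * keep))
}

ad_recip <- function(a) {
  v <- a$val
  ad_node(a$tape, 1 / v, list(a), function(g) list(-g / (v * v)))
}

## ---- shape ops ------------------------------------------------------------

ad_cbind <- function(nodes) {
  vals <- lapply(nodes, function(e) e$val)
  ncols <- vapply(vals, ncol, 1L)
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  ad_node(nodes[[1]]$tape, do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ad_rbind <- function(nodes) {
  vals <- lapply(nodes, function(e) e$val)
  nrows <- vapply(vals, nrow, 1L)
  ends <- cumsum(nrows)
  starts <- ends - nrows + 1L
  ad_node(nodes[[1]]$tape, do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

# Gather rows (indices may repeat; backward scatter-adds).
ad_rows <- function(a, idx) {
  va <- a$val
  nr <- nrow(va); nc <- ncol(va)
  ad_node(a$tape, va[idx, , drop = FALSE], list(a), function(g) {
    z <- matrix(0, nr, nc)
    agg <- rowsum(g, group = idx)
    z[as.integer(rownames(agg)), ] <- agg
    list(z)
  })
}

# Gather distinct columns.
ad_cols <- function(a, idx) {
  va <- a$val
  nr <- nrow(va); nc <- ncol(va)
  ad_node(a$tape, va[, idx, drop = FALSE], list(a), function(g) {
    z <- matrix(0, nr, nc)
    z[, idx] <- g
    list(z)
  })
}

ad_t <- function(a) {
  ad_node(a$tape, t(a$val), list(a), function(g) list(t(g)))
}

# Scatter a column of P values into an n x n matrix at (ri, ci); the index
# pairs must be distinct.
ad_scatter <- function(vals, ri, ci, n) {
  v <- as.vector(vals$val)
  m <- matrix(0, n, n)
  m[cbind(ri, ci)] <- v
  ad_node(vals$tape, m, list(vals),
          function(g) list(matrix(g[cbind(ri, ci)], ncol = 1L)))
}

## ---- reductions and softmax -----------------------------------------------

ad_sum <- function(a) {
  va <- a$val
  ad_node(a$tape, sum(va), list(a), function(g) {
    if (is.matrix(va)) list(matrix(g, nrow(va), ncol(va))) else list(rep(g, length(va)))
  })
}

ad_rowsum <- function(a) {
  va <- a$val
  nc <- ncol(va)
  ad_node(a$tape, matrix(rowSums(va), ncol = 1L), list(a),
          function(g) list(matrix(as.vector(g), nrow(va), nc)))
}

# Row-wise softmax with an optional additive mask (e.g. -1e30 outside a
# block-diagonal support, which zeroes cross-block attention exactly).
ad_rowsoftmax <- function(a, addmask = NULL) {
  z <- a$val
  if (!is.null(addmask)) z <- z + addmask
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  ad_node(a$tape, p, list(a), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

## ---- fused operations ------------------------------------------------------
# Coarse-grained nodes with hand-written backward passes. Training unrolls a
# recurrent network over many steps; fusing whole layers into single nodes
# keeps the tape short, which dominates CPU cost. Raw (non-node) matrix
# arguments are constants of the graph and receive no gradient.

.node_or_val <- function(x) if (is.environment(x)) x$val else x

# affine: x W + b  (b a bias vector)
ad_affine <- function(x, W, b) {
  vx <- x$val; vW <- W$val; vb <- b$val
  out <- vx %*% vW
  out <- out + rep(vb, each = nrow(out))
  ad_node(x$tape, out, list(x, W, b), function(g) {
    list(g %*% t(vW), crossprod(vx, g), colSums(g))
  })
}

# filler as a single node: a + b * y with constant matrices a, b
ad_fill <- function(y, a_mat, b_mat) {
  ad_node(y$tape, a_mat + b_mat * y$val, list(y), function(g) list(g * b_mat))
}

# constant-left matrix product: M x
ad_lmm <- function(tape, M, x) {
  ad_node(tape, M %*% x$val, list(x), function(g) list(crossprod(M, g)))
}

# column concatenation of nodes and constant matrices in one tape node
ad_catx <- function(tape, items) {
  vals <- lapply(items, .node_or_val)
  ncols <- vapply(vals, ncol, 1L)
  ends <- cumsum(ncols); starts <- ends - ncols + 1L
  is_node <- vapply(items, is.environment, TRUE)
  parents <- items[is_node]
  ad_node(tape, do.call(cbind, vals), parents, function(g) {
    lapply(which(is_node), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# full GRU cell: gates ordered [update, reset, candidate]; x may be a node
# or a constant matrix
ad_gru <- function(x, h, Wx, Wh, bx, bh, dh) {
  vx <- .node_or_val(x); vh <- h$val
  vWx <- Wx$val; vWh <- Wh$val
  px <- vx %*% vWx; px <- px + rep(bx$val, each = nrow(px))
  ph <- vh %*% vWh; ph <- ph + rep(bh$val, each = nrow(ph))
  iz <- seq_len(dh); ir <- dh + iz; ic <- 2L * dh + iz
  zg <- 1 / (1 + exp(-(px[, iz, drop = FALSE] + ph[, iz, drop = FALSE])))
  rg <- 1 / (1 + exp(-(px[, ir, drop = FALSE] + ph[, ir, drop = FALSE])))
  phc <- ph[, ic, drop = FALSE]
  cand <- tanh(px[, ic, drop = FALSE] + rg * phc)
  out <- vh + zg * (cand - vh)
  x_is_node <- is.environment(x)
  parents <- c(if (x_is_node) list(x), list(h, Wx, Wh, bx, bh))
  ad_node(h$tape, out, parents, function(g) {
    dz <- g * (cand - vh)
    dc <- g * zg
    dh_direct <- g * (1 - zg)
    dpc <- dc * (1 - cand * cand)
    dr <- dpc * phc
    dpz <- dz * zg * (1 - zg)
    dpr <- dr * rg * (1 - rg)
    dpx <- cbind(dpz, dpr, dpc)
    dph <- cbind(dpz, dpr, dpc * rg)
    dhh <- dh_direct + dph %*% t(vWh)
    out_g <- list(dhh,
                  crossprod(vx, dpx), crossprod(vh, dph),
                  colSums(dpx), colSums(dph))
    if (x_is_node) c(list(dpx %*% t(vWx)), out_g) else out_g
  })
}

# one scaled-dot-product attention head with additive mask (constant)
ad_attn_head <- function(C, Wq, Wk, Wv, scale, addmask) {
  vC <- C$val; vWq <- Wq$val; vWk <- Wk$val; vWv <- Wv$val
  Q <- vC %*% vWq; K <- vC %*% vWk; V <- vC %*% vWv
  S <- tcrossprod(Q, K) * scale + addmask
  S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S)
  P <- E / rowSums(E)
  out <- P %*% V
  ad_node(C$tape, out, list(C, Wq, Wk, Wv), function(g) {
    dV <- crossprod(P, g)
    dP <- tcrossprod(g, V)
    dS <- P * (dP - rowSums(dP * P))
    dQ <- (dS %*% K) * scale
    dK <- crossprod(dS, Q) * scale
    dC <- dQ %*% t(vWq) + dK %*% t(vWk) + dV %*% t(vWv)
    list(dC, crossprod(vC, dQ), crossprod(vC, dK), crossprod(vC, dV))
  })
}

# degree-normalized message passing: relu(D^-1 A U W1 + U W2 + b),
# weighted degree clamped at 1
ad_prop_fused <- function(U, A, W1, W2, b) {
  vU <- U$val; vA <- A$val; vW1 <- W1$val; vW2 <- W2$val
  rs <- rowSums(vA)
  dcl <- pmax(rs, 1)
  inv <- 1 / dcl
  Pn <- vA * inv
  M <- Pn %*% vU
  pre <- M %*% vW1 + vU %*% vW2
  pre <- pre + rep(b$val, each = nrow(pre))
  pos <- pre > 0
  ad_node(U$tape, pre * pos, list(U, A, W1, W2, b), function(g) {
    dpre <- g * pos
    dM <- dpre %*% t(vW1)
    dU <- dpre %*% t(vW2) + crossprod(Pn, dM)
    dPn <- tcrossprod(dM, vU)
    dA <- dPn * inv
    dinv <- rowSums(dPn * vA)
    unclamped <- rs > 1
    dA <- dA + (unclamped * (-inv * inv) * dinv)   # recycled down rows
    list(dU, dA, crossprod(M, dpre), crossprod(vU, dpre), colSums(dpre))
  })
}

# gather + concatenate pair features [U_i, U_j, H_i, H_j, tpair]
ad_paircat <- function(U, H, tpair, pair_i, pair_j) {
  vU <- U$val; vH <- H$val; vt <- tpair$val
  du <- ncol(vU); dhc <- ncol(vH)
  out <- cbind(vU[pair_i, , drop = FALSE], vU[pair_j, , drop = FALSE],
               vH[pair_i, , drop = FALSE], vH[pair_j, , drop = FALSE], vt)
  scat <- function(g_part, idx, nr) {
    z <- matrix(0, nr, ncol(g_part))
    agg <- rowsum(g_part, group = idx)
    z[as.integer(rownames(agg)), ] <- agg
    z
  }
  ad_node(U$tape, out, list(U, H, tpair), function(g) {
    gU <- scat(g[, seq_len(du), drop = FALSE], pair_i, nrow(vU)) +
      scat(g[, du + seq_len(du), drop = FALSE], pair_j, nrow(vU))
    gH <- scat(g[, 2 * du + seq_len(dhc), drop = FALSE], pair_i, nrow(vH)) +
      scat(g[, 2 * du + dhc + seq_len(dhc), drop = FALSE], pair_j, nrow(vH))
    list(gU, gH, g[, 2 * du + 2 * dhc + seq_len(ncol(vt)), drop = FALSE])
  })
}

# scatter pair scores into the adjacency and symmetrize in one node
ad_scatter_sym <- function(vals, ri, ci, n, undirected) {
  v <- as.vector(vals$val)
  m <- matrix(0, n, n)
  m[cbind(ri, ci)] <- v
  if (undirected) m <- (m + t(m)) / 2
  ad_node(vals$tape, m, list(vals), function(g) {
    gv <- if (undirected) (g[cbind(ri, ci)] + g[cbind(ci, ri)]) / 2
          else g[cbind(ri, ci)]
    list(matrix(gv, ncol = 1L))
  })
}

# Bochner code for a vector of timestamps: interleaved cos/sin over learnable
# frequencies, scaled to unit norm
ad_timecode <- function(w, tvec, k) {
  vw <- w$val
  ang <- tvec %*% vw                      # W x k
  sc <- 1 / sqrt(k)
  idx <- as.vector(rbind(seq_len(k), k + seq_len(k)))
  code <- cbind(cos(ang), sin(ang))[, idx, drop = FALSE] * sc
  ad_node(w$tape, code, list(w), function(g) {
    gc <- matrix(0, nrow(g), 2L * k)
    gc[, idx] <- g
    dang <- (-sin(ang) * gc[, seq_len(k), drop = FALSE] +
               cos(ang) * gc[, k + seq_len(k), drop = FALSE]) * sc
    list(crossprod(tvec, dang))
  })
}

# sum(mask * |label - pred|) with constant mask/label
ad_masked_abs_sum <- function(pred, label, mask) {
  d <- (pred$val - label) * mask
  ad_node(pred$tape, sum(abs(d)), list(pred),
          function(g) list(g * sign(d) * mask))
}

# sum(mask * (label - pred)^2) with constant mask/label
ad_masked_sq_sum <- function(pred, label, mask) {
  d <- (pred$val - label) * mask
  ad_node(pred$tape, sum(d * d), list(pred), function(g) list(2 * g * d * mask))
}

# KL(q || N(0, I)) summed over entries: 0.5 sum(mu^2 + exp(lv) - lv - 1)
ad_kl_sum <- function(mu, lv) {
  vmu <- mu$val; vlv <- lv$val
  elv <- exp(vlv)
  ad_node(mu$tape, 0.5 * sum(vmu * vmu + elv - vlv - 1), list(mu, lv),
          function(g) list(g * vmu, g * 0.5 * (elv - 1)))
}
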