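#' Synthetic NTS generator configuration
#'
#' The generator produces a complete (fully observed) networked time series
#' with the statistical structure the imputation model targets: smooth,
#' spatially correlated node signals on a static proximity graph, dynamic
#' edge weights obtained by thresholding a radial-basis similarity of the
#' endpoint signals, and masks that hide features at random and edges by the
#' endpoint rule (an edge is unobservable whenever either incident node is
#' unobserved) or with a fixed drop probability.
#'
#' @param N,T,D nodes, time steps, features.
#' @param base_graph \code{"geometric"} (random points in the unit square,
#'   thresholded Gaussian-kernel weights), \code{"erdos_renyi"} or
#'   \code{"grid"}.
#' @param rank number of latent smooth temporal factors.
#' @param smoothness Gaussian smoothing bandwidth of the factors, in steps.
#' @param coupling neighbor-averaging strength in \code{[0, 1)} mixing each
#'   node's signal with its graph neighborhood (makes adjacent series
#'   correlated).
#' @param noise_sd additive Gaussian observation noise.
#' @param rbf_sigma bandwidth of the edge-dynamics similarity.
#' @param threshold dynamics threshold \code{k}: an edge is present at
#'   \code{t} only while the endpoint similarity exceeds \code{k};
#'   \code{k = 0} disables the dynamics (static edges).
#' @param node_missing_rate i.i.d. probability \code{p} of hiding a feature
#'   entry.
#' @param edge_rule \code{"endpoint"}, \code{"drop70"} (endpoint-eligible
#'   edges hidden with probability 0.7) or \code{"none"}.
#' @param geo_radius connection radius of the geometric graph.
#' @param er_prob edge probability of the Erdos-Renyi graph.
#' @param seed integer seed; the whole generation is deterministic in it.
#' @return a \code{nts_generator_config} list.
#' @export
generator_config <- function(N = 12L, T = 200L, D = 1L,
                             base_graph = c("geometric", "erdos_renyi", "grid"),
                             rank = 3L, smoothness = 10, coupling = 0.6,
                             noise_sd = 0.1, rbf_sigma = 1.0, threshold = 0.3,
                             node_missing_rate = 0.25,
                             edge_rule = c("endpoint", "drop70", "none"),
                             geo_radius = 0.5, er_prob = 0.3, seed = 0L) {
  base_graph <- match.arg(base_graph)
  edge_rule <- match.arg(edge_rule)
  if (node_missing_rate < 0 || node_missing_rate >= 1)
    stop("node_missing_rate must lie in [0, 1)")
  if (threshold < 0) stop("threshold must be >= 0")
  if (rbf_sigma <= 0) stop("rbf_sigma must be > 0")
  if (coupling < 0 || coupling >= 1) stop("coupling must lie in [0, 1)")
  structure(list(N = as.integer(N), T = as.integer(T), D = as.integer(D),
                 base_graph = base_graph, rank = as.integer(rank),
                 smoothness = smoothness, coupling = coupling,
                 noise_sd = noise_sd, rbf_sigma = rbf_sigma,
                 threshold = threshold,
                 node_missing_rate = node_missing_rate,
                 edge_rule = edge_rule, geo_radius = geo_radius,
                 er_prob = er_prob, seed = as.integer(seed)),
            class = "nts_generator_config")
}

#' Radial-basis similarity of two feature vectors
#'
#' \code{exp(-||x_u - x_v||^2 / (2 sigma^2))}: 1 for identical vectors,
#' strictly decreasing in distance, in \code{(0, 1]}.
#'
#' @param x_u,x_v numeric vectors of equal length.
#' @param sigma bandwidth, \code{> 0}.
#' @return scalar in \code{(0, 1]}.
#' @export
rbf_similarity <- function(x_u, x_v, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  exp(-sum((x_u - x_v)^2) / (2 * sigma^2))
}

# Static weighted base graph: symmetric, zero diagonal.
.base_graph <- function(config) {
  N <- config$N
  A <- matrix(0, N, N)
  if (config$base_graph == "geometric") {
    pts <- matrix(stats::runif(2 * N), N, 2)
    dmat <- as.matrix(stats::dist(pts))
    sw <- config$geo_radius / 2
    A <- exp(-dmat^2 / (2 * sw^2)) * (dmat < config$geo_radius)
    diag(A) <- 0
  } else if (config$base_graph == "erdos_renyi") {
    for (i in seq_len(N - 1)) for (j in seq.int(i + 1, N)) {
      if (stats::runif(1) < config$er_prob) {
        w <- stats::runif(1, 0.5, 1.5)
        A[i, j] <- w; A[j, i] <- w
      }
    }
  } else {
    side <- ceiling(sqrt(N))
    for (i in seq_len(N)) {
      ri <- (i - 1) %/% side; ci <- (i - 1) %% side
      for (j in seq_len(N)) {
        rj <- (j - 1) %/% side; cj <- (j - 1) %% side
        if (abs(ri - rj) + abs(ci - cj) == 1) A[i, j] <- 1
      }
    }
  }
  A
}

# Smooth standardized temporal factor via Gaussian kernel smoothing of white
# noise; bandwidth in time steps.
.smooth_factor <- function(T, bw) {
  half <- max(1L, ceiling(3 * bw))
  kern <- stats::dnorm(seq(-half, half), sd = bw)
  kern <- kern / sum(kern)
  raw <- stats::rnorm(T + 2 * half)
  sm <- stats::filter(raw, kern, sides = 2)
  sm <- as.numeric(sm[(half + 1):(half + T)])
  as.numeric(scale(sm))
}

#' Generate a ground-truth NTS and its partially observed bundle
#'
#' Pipeline: (1) sample the static base graph; (2) draw node signals as
#' random loadings on \code{rank} smooth temporal factors, mix each node
#' with its graph neighborhood (\code{coupling}) so adjacent series
#' correlate, restandardize per node, add observation noise; (3) form the
#' dynamic adjacency: a base edge carries its static weight at time \code{t}
#' only while the radial-basis similarity of its endpoint signals exceeds
#' \code{threshold}; (4) hide feature entries i.i.d. and edges by
#' \code{edge_rule} via \code{\link{apply_masks}}.
#'
#' @param config a \code{\link{generator_config}}.
#' @return object of class \code{nts_ground_truth}: \code{truth} (complete
#'   \code{features}, \code{adjacency}, \code{timestamps}), \code{bundle}
#'   (the partially observed \code{nts_bundle}), \code{eval_feature_mask}
#'   and \code{eval_edge_mask} (1 exactly at hidden entries), \code{config}.
#' @export
generate_nts <- function(config = generator_config()) {
  N <- config$N; T <- config$T; D <- config$D
  truth <- .with_seed(config$seed, {
    base <- .base_graph(config)
    x <- array(0, c(T, N, D))
    for (d in seq_len(D)) {
      Fm <- sapply(seq_len(config$rank), function(r)
        .smooth_factor(T, config$smoothness))
      lam <- matrix(stats::rnorm(N * config$rank), N)
      xd <- Fm %*% t(lam) / sqrt(config$rank)   # T x N
      if (config$coupling > 0) {
        deg <- pmax(rowSums(base), 1e-12)
        P <- base / deg
        for (round in 1:2)
          xd <- (1 - config$coupling) * xd + config$coupling * xd %*% t(P)
      }
      xd <- apply(xd, 2, function(v)
        if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v)
      xd <- xd + matrix(stats::rnorm(T * N, sd = config$noise_sd), T, N)
      x[, , d] <- xd
    }
    a <- array(0, c(T, N, N))
    eidx <- which(base != 0, arr.ind = TRUE)
    for (t in seq_len(T)) {
      at <- matrix(0, N, N)
      if (nrow(eidx)) {
        xt <- matrix(x[t, , ], N, D)
        for (q in seq_len(nrow(eidx))) {
          u <- eidx[q, 1]; v <- eidx[q, 2]
          if (u < v) {
            keep <- config$threshold == 0 ||
              rbf_similarity(xt[u, ], xt[v, ], config$rbf_sigma) >
                config$threshold
            if (keep) { at[u, v] <- base[u, v]; at[v, u] <- base[v, u] }
          }
        }
      }
      a[t, , ] <- at
    }
    list(features = x, adjacency = a, timestamps = seq_len(T) - 1,
         node_ids = paste0("n", seq_len(N) - 1L),
         feature_names = paste0("f", seq_len(D) - 1L))
  })
  masked <- apply_masks(truth, p = config$node_missing_rate,
                        edge_rule = config$edge_rule,
                        seed = config$seed + 1L)
  structure(list(truth = truth, bundle = masked$bundle,
                 eval_feature_mask = masked$eval_feature_mask,
                 eval_edge_mask = masked$eval_edge_mask,
                 config = config),
            class = "nts_ground_truth")
}

#' Hide entries of a complete NTS
#'
#' Feature entries are hidden i.i.d. with probability \code{p}. A node
#' counts as missing at time \code{t} when all of its feature entries are
#' hidden there (for \code{D = 1} this is per-entry masking). Edge hiding:
#' \code{"endpoint"} hides every pair \code{(u, v, t)} with a missing
#' endpoint; \code{"drop70"} hides such pairs with probability 0.7;
#' \code{"none"} hides nothing. Hidden entries form the evaluation masks,
#' which are exactly the complement of the observation masks on the hidden
#' set.
#'
#' @param truth list with \code{features} (\code{T x N x D}),
#'   \code{adjacency} (\code{T x N x N}), \code{timestamps}, and optional
#'   \code{node_ids}, \code{feature_names}.
#' @param p feature missing probability in \code{[0, 1)}.
#' @param edge_rule \code{"endpoint"}, \code{"drop70"} or \code{"none"}.
#' @param seed RNG seed for the mask draws.
#' @return list: \code{bundle} (an \code{nts_bundle} with \code{NA} at
#'   hidden entries), \code{eval_feature_mask}, \code{eval_edge_mask}.
#' @export
apply_masks <- function(truth, p, edge_rule = c("endpoint", "drop70", "none"),
                        seed = 0L) {
  edge_rule <- match.arg(edge_rule)
  if (p < 0 || p >= 1) stop("p must lie in [0, 1)")
  dims <- dim(truth$features)
  T <- dims[1]; N <- dims[2]; D <- dims[3]
  .with_seed(seed, {
    fmask <- array(as.numeric(stats::runif(T * N * D) >= p), dims)
    node_obs <- apply(fmask, c(1, 2), max)   # 1 if any feature observed
    emask <- array(1, c(T, N, N))
    if (edge_rule != "none") {
      for (t in seq_len(T)) {
        miss <- node_obs[t, ] == 0
        hide <- outer(miss, miss, "|")
        diag(hide) <- FALSE
        if (edge_rule == "drop70") {
          hid_idx <- which(hide & upper.tri(hide), arr.ind = TRUE)
          if (nrow(hid_idx)) {
            keep <- stats::runif(nrow(hid_idx)) >= 0.7
            hide[hid_idx[keep, , drop = FALSE]] <- FALSE
            hide[hid_idx[keep, c(2, 1), drop = FALSE]] <- FALSE
            hide[hid_idx[!keep, , drop = FALSE]] <- TRUE
            hide[hid_idx[!keep, c(2, 1), drop = FALSE]] <- TRUE
          }
        }
        emask[t, , ][hide] <- 0
      }
    }
    x <- truth$features
    x[fmask == 0] <- NA_real_
    a <- truth$adjacency
    a[emask == 0] <- NA_real_
    bundle <- nts_bundle(x, a, fmask, emask, truth$timestamps,
                         node_ids = truth$node_ids,
                         feature_names = truth$feature_names,
                         undirected = TRUE, absent_edge = "zero")
    list(bundle = bundle,
         eval_feature_mask = 1 - fmask,
         eval_edge_mask = 1 - emask)
  })
}
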