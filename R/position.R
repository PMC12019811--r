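#' Random-walk-with-restart scores of all nodes against one anchor
#'
#' Computes the personalized-PageRank vector \code{r} solving
#' \code{r = (1 - c) W r + c e_anchor}, where \code{W} is the column-stochastic
#' transition matrix of the weighted graph: \code{W[u, v] = A[u, v] / deg(v)}
#' with \code{deg(v)} the weighted degree of \code{v}. Columns of zero degree
#' (dangling nodes) restart to the anchor, which keeps \code{W}
#' column-stochastic, so the score vector is a probability distribution:
#' nonnegative and summing to one. Solved by power iteration, which contracts
#' at rate \code{1 - c} in the L1 norm.
#'
#' @param adjacency nonnegative \code{N x N} weight matrix (zero diagonal
#'   allowed; symmetric for undirected graphs).
#' @param anchor 1-based anchor node index.
#' @param c restart probability in \code{(0, 1]}.
#' @param eps convergence tolerance: iteration stops when successive iterates
#'   differ by less than \code{eps} in the max norm.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return numeric vector of \code{N} scores, \code{>= 0}, summing to 1.
#' @export
rwr_scores <- function(adjacency, anchor, c = 0.15, eps = 1e-8,
                       max_iter = 10000L) {
  if (!is.numeric(c) || length(c) != 1 || c <= 0 || c > 1)
    stop("restart probability c must lie in (0, 1]")
  n <- nrow(adjacency)
  if (!is.matrix(adjacency) || ncol(adjacency) != n)
    stop("adjacency must be a square matrix")
  if (anchor < 1 || anchor > n) stop("anchor index out of range")
  if (any(adjacency < 0)) stop("adjacency must be nonnegative")
  e <- numeric(n); e[anchor] <- 1
  if (c == 1) return(e)
  W <- .rwr_transition(adjacency, anchor)
  r <- e
  for (i in seq_len(max_iter)) {
    r_new <- (1 - c) * as.vector(W %*% r) + c * e
    if (max(abs(r_new - r)) < eps) return(r_new)
    r <- r_new
  }
  stop(sprintf("RWR did not converge within %d iterations", max_iter))
}

# Column-stochastic transition matrix; dangling columns restart to the anchor.
.rwr_transition <- function(adjacency, anchor) {
  deg <- colSums(adjacency)
  W <- adjacency
  nz <- deg > 0
  W[, nz] <- sweep(adjacency[, nz, drop = FALSE], 2L, deg[nz], "/")
  if (any(!nz)) {
    W[, !nz] <- 0
    W[anchor, !nz] <- 1
  }
  W
}

#' Select the anchor node set for position embeddings
#'
#' Position embeddings score every node against a small set of anchors. The
#' \code{degree_top} strategy takes the \code{L} nodes with the largest total
#' observed weighted degree summed over the window (ties broken by smaller
#' node index); \code{random} draws a seed-deterministic uniform sample
#' without replacement.
#'
#' @param window an \code{nts_window} or \code{nts_bundle}.
#' @param L number of anchors, \code{1 <= L <= N}. Default
#'   \code{min(N, ceiling(log2(N))^2)}.
#' @param strategy \code{"degree_top"} or \code{"random"}.
#' @param seed integer seed used by the random strategy.
#' @return list with \code{anchor_indices} (1-based, length \code{L}),
#'   \code{strategy} and \code{selection_seed}, of class \code{nts_anchors}.
#' @export
select_anchors <- function(window, L = NULL,
                           strategy = c("degree_top", "random"), seed = 0L) {
  strategy <- match.arg(strategy)
  d <- nts_dim(window)
  n <- unname(d[2])
  if (is.null(L)) L <- min(n, ceiling(log2(max(n, 2)))^2)
  if (L < 1 || L > n) stop(sprintf("anchor count L=%d outside 1..N=%d", L, n))
  idx <- if (strategy == "degree_top") {
    deg <- numeric(n)
    for (t in seq_len(d[1])) deg <- deg + rowSums(.observed_adjacency(window, t))
    order(-deg, seq_len(n))[seq_len(L)]
  } else {
    .with_seed(seed, sample.int(n, L))
  }
  structure(list(anchor_indices = as.integer(idx), strategy = strategy,
                 selection_seed = as.integer(seed)),
            class = "nts_anchors")
}

#' Build the RWR position tensor for a window
#'
#' For each time step \code{t} and anchor \code{j},
#' \code{scores[t, , j]} is the RWR score vector of all nodes against that
#' anchor on the observed graph at step \code{t} (masked-out edges enter with
#' weight 0). These per-anchor personalized-PageRank profiles are the
#' structural position features consumed by the encoder and decoder.
#'
#' @param window an \code{nts_window} or \code{nts_bundle}.
#' @param anchors an \code{nts_anchors} from \code{\link{select_anchors}}.
#' @param c restart probability.
#' @param eps power-iteration tolerance.
#' @return list of class \code{nts_positions}: \code{scores}
#'   (\code{T x N x L} array), \code{anchors}, \code{c}, \code{eps}.
#' @export
build_position_tensor <- function(window, anchors, c = 0.15, eps = 1e-8) {
  d <- nts_dim(window)
  idx <- anchors$anchor_indices
  if (any(idx < 1 | idx > d[2])) stop("anchor indices out of range for window")
  scores <- array(0, c(d[1], d[2], length(idx)))
  for (t in seq_len(d[1])) {
    at <- .observed_adjacency(window, t)
    for (j in seq_along(idx)) {
      scores[t, , j] <- rwr_scores(at, idx[j], c = c, eps = eps)
    }
  }
  structure(list(scores = scores, anchors = anchors, c = c, eps = eps),
            class = "nts_positions")
}

#' 1-Weisfeiler-Lehman color refinement
#'
#' Iteratively refines node colors by hashing each node's color together with
#' the multiset of its neighbors' colors (edge weights are used only through
#' the binary support). Message-passing graph networks cannot distinguish
#' nodes that 1-WL assigns the same color; RWR position scores can, which is
#' the expressiveness gap this package's tests demonstrate on the 6-cycle.
#'
#' @param adjacency \code{N x N} weight matrix; nonzero entries are edges.
#' @param max_iter maximum refinement rounds (defaults to \code{N}).
#' @return integer vector of color classes, 1-based and dense.
#' @export
wl_colors <- function(adjacency, max_iter = nrow(adjacency)) {
  n <- nrow(adjacency)
  nbr <- lapply(seq_len(n), function(i) which(adjacency[i, ] != 0))
  colors <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    sigs <- vapply(seq_len(n), function(i) {
      paste(colors[i], paste(sort(colors[nbr[[i]]]), collapse = ","), sep = "|")
    }, character(1))
    new_colors <- match(sigs, unique(sigs))
    if (identical(new_colors, colors)) break
    colors <- new_colors
  }
  colors
}

# Evaluate an expression with a temporary RNG state, restoring the caller's.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
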