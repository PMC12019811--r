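#' Masked imputation metrics
#'
#' Computes error metrics of an imputation strictly on the held-out
#' (evaluation) entries: MAE, MSE, MRE (sum of absolute errors divided by
#' the sum of absolute label magnitudes; 0 when the denominator is 0) for
#' features, and the Frobenius norm of the adjacency error on evaluated edge
#' entries. Entries outside the evaluation masks never influence the result.
#'
#' @param filled an \code{nts_imputation} or a list with \code{features}
#'   (\code{T x N x D}) and optionally \code{adjacency} (\code{T x N x N}).
#' @param truth list with complete \code{features} and \code{adjacency}.
#' @param eval_masks list with \code{features} (\code{T x N x D}) and
#'   optionally \code{edges} (\code{T x N x N}), binary, 1 = evaluate here.
#' @param bundle optional \code{nts_bundle}; when given, the evaluation
#'   masks are checked to be disjoint from its observation masks (an overlap
#'   is a contract error: a model must never be scored on entries it saw).
#' @return list of class \code{nts_metrics}: \code{mae}, \code{mse},
#'   \code{mre}, \code{link_frobenius}, \code{n_eval_feature_entries},
#'   \code{n_eval_edge_entries}.
#' @export
evaluate_imputation <- function(filled, truth, eval_masks, bundle = NULL) {
  fm <- eval_masks$features
  if (!is.null(bundle)) {
    if (any(fm == 1 & bundle$feature_mask == 1))
      stop("evaluation mask overlaps the observation mask (features)")
    if (!is.null(eval_masks$edges) &&
        any(eval_masks$edges == 1 & bundle$edge_mask == 1))
      stop("evaluation mask overlaps the observation mask (edges)")
  }
  err <- filled$features - truth$features
  err[fm == 0] <- 0
  n_f <- sum(fm)
  mae <- sum(abs(err)) / max(n_f, 1)
  mse <- sum(err^2) / max(n_f, 1)
  lab <- abs(truth$features)
  lab[fm == 0] <- 0
  mre <- if (sum(lab) > 0) sum(abs(err)) / sum(lab) else 0
  lf <- 0; n_e <- 0
  if (!is.null(eval_masks$edges) && !is.null(filled$adjacency)) {
    n_e <- sum(eval_masks$edges)
    lf <- link_frobenius(filled$adjacency, truth$adjacency, eval_masks$edges)
  }
  structure(list(mae = mae, mse = mse, mre = mre, link_frobenius = lf,
                 n_eval_feature_entries = n_f, n_eval_edge_entries = n_e),
            class = "nts_metrics")
}

#' Node-mean imputation baseline
#'
#' Replaces each missing feature entry \code{(t, u, d)} with the mean of
#' node \code{u}'s observed values of feature \code{d} over the whole
#' sequence; a node-feature with no observations at all falls back to the
#' global observed mean of that feature (0 if the feature is entirely
#' unobserved). Observed entries are returned unchanged.
#'
#' @param bundle an \code{nts_bundle}.
#' @return \code{T x N x D} array of filled features.
#' @export
mean_baseline <- function(bundle) {
  d <- nts_dim(bundle)
  x <- bundle$features
  m <- bundle$feature_mask
  out <- x
  for (dd in seq_len(d[3])) {
    xd <- matrix(x[, , dd], d[1], d[2])
    md <- matrix(m[, , dd], d[1], d[2])
    xd[md == 0] <- NA
    node_means <- colMeans(xd, na.rm = TRUE)
    global <- mean(xd, na.rm = TRUE)
    if (!is.finite(global)) global <- 0
    node_means[!is.finite(node_means)] <- global
    fill <- matrix(node_means, d[1], d[2], byrow = TRUE)
    xd[md == 0] <- fill[md == 0]
    out[, , dd] <- xd
  }
  out
}
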