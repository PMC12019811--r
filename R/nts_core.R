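#' Construct a partially observed networked time series bundle
#'
#' A networked time series (NTS) couples a multivariate time series (a
#' \code{T x N x D} feature tensor over \code{N} nodes and \code{D} features)
#' with a sequence of \code{T} weighted adjacency matrices over the same
#' nodes. Both parts can be partially observed: binary masks mark each feature
#' entry and each edge entry as observed (1) or missing (0). Values stored at
#' masked-out entries are ignored by every computation in the package and may
#' be \code{NA}.
#'
#' The constructor performs structural checks only (shapes, types, mask
#' domain); value-level problems such as negative observed weights are
#' reported by \code{\link{validate_bundle}} so that defective data can still
#' be inspected.
#'
#' @param features numeric array \code{T x N x D}; \code{NA} allowed wherever
#'   \code{feature_mask} is 0.
#' @param adjacency numeric array \code{T x N x N} of edge weights.
#' @param feature_mask,edge_mask binary arrays matching \code{features} and
#'   \code{adjacency}; 1 = observed, 0 = missing.
#' @param timestamps strictly increasing numeric vector of length \code{T}.
#' @param node_ids,feature_names character labels (defaults generated).
#' @param undirected logical; when \code{TRUE} edges are treated as symmetric.
#' @param absent_edge how an edge pair absent from an edge list on disk is
#'   interpreted: \code{"zero"} (observed weight 0, the default) or
#'   \code{"missing"} (mask 0).
#' @return an object of class \code{nts_bundle}.
#' @export
nts_bundle <- function(features, adjacency, feature_mask, edge_mask,
                       timestamps, node_ids = NULL, feature_names = NULL,
                       undirected = TRUE, absent_edge = c("zero", "missing")) {
  absent_edge <- match.arg(absent_edge)
  if (length(dim(features)) != 3L)
    stop("features must be a T x N x D array")
  dT <- dim(features)[1]; dN <- dim(features)[2]; dD <- dim(features)[3]
  if (!identical(dim(adjacency), c(dT, dN, dN)))
    stop("adjacency must be a T x N x N array matching features")
  if (!identical(dim(feature_mask), dim(features)))
    stop("feature_mask shape must match features")
  if (!identical(dim(edge_mask), dim(adjacency)))
    stop("edge_mask shape must match adjacency")
  if (length(timestamps) != dT)
    stop("timestamps must have length T")
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(dN) - 1L)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(dD) - 1L)
  if (length(node_ids) != dN) stop("node_ids must have length N")
  if (length(feature_names) != dD) stop("feature_names must have length D")
  structure(list(
    features = features, adjacency = adjacency,
    feature_mask = feature_mask, edge_mask = edge_mask,
    timestamps = as.numeric(timestamps),
    node_ids = as.character(node_ids),
    feature_names = as.character(feature_names),
    undirected = isTRUE(undirected), absent_edge = absent_edge
  ), class = "nts_bundle")
}

#' Dimensions of an NTS bundle
#' @param bundle an \code{nts_bundle}.
#' @return integer vector \code{c(T, N, D)}.
#' @export
nts_dim <- function(bundle) {
  c(T = dim(bundle$features)[1], N = dim(bundle$features)[2],
    D = dim(bundle$features)[3])
}

#' @export
print.nts_bundle <- function(x, ...) {
  d <- nts_dim(x)
  obs_f <- mean(x$feature_mask)
  obs_e <- mean(x$edge_mask)
  cat(sprintf(
    "<nts_bundle> T=%d N=%d D=%d (%s)\n  features observed: %.1f%%  edges observed: %.1f%%\n",
    d[1], d[2], d[3], if (x$undirected) "undirected" else "directed",
    100 * obs_f, 100 * obs_e))
  invisible(x)
}

#' Validate an NTS bundle
#'
#' Checks every bundle invariant and reports per-check pass/fail with the
#' number of offending entries. Never raises; use it to audit data before
#' training. Checks: masks binary; observed feature values finite; observed
#' edge weights finite and nonnegative; adjacency diagonal zero; timestamps
#' strictly increasing; observed adjacency symmetric when the bundle is
#' undirected.
#'
#' @param bundle an \code{nts_bundle}.
#' @return a data.frame with columns \code{check}, \code{pass},
#'   \code{n_offenders}.
#' @export
validate_bundle <- function(bundle) {
  fm <- bundle$feature_mask; em <- bundle$edge_mask
  x <- bundle$features; a <- bundle$adjacency
  d <- nts_dim(bundle)
  checks <- list()
  add <- function(name, n_off) checks[[length(checks) + 1L]] <<-
      data.frame(check = name, pass = n_off == 0L, n_offenders = n_off)

  add("feature_mask_binary", sum(!(fm %in% c(0, 1))))
  add("edge_mask_binary", sum(!(em %in% c(0, 1))))
  add("observed_features_finite", sum(fm == 1 & !is.finite(x)))
  add("observed_edges_finite", sum(em == 1 & !is.finite(a)))
  add("observed_edges_nonnegative", sum(em == 1 & is.finite(a) & a < 0))
  diag_idx <- cbind(rep(seq_len(d[1]), d[2]),
                    rep(seq_len(d[2]), each = d[1]),
                    rep(seq_len(d[2]), each = d[1]))
  add("adjacency_diagonal_zero",
      sum(em[diag_idx] == 1 & a[diag_idx] != 0, na.rm = TRUE))
  add("timestamps_strictly_increasing",
      if (d[1] > 1) sum(diff(bundle$timestamps) <= 0) else 0L)
  if (bundle$undirected) {
    n_asym <- 0L
    for (t in seq_len(d[1])) {
      at <- a[t, , ]; mt <- em[t, , ]
      both <- mt == 1 & t(mt) == 1
      dif <- both & is.finite(at) & is.finite(t(at)) & at != t(at)
      n_asym <- n_asym + sum(dif[upper.tri(dif)])
    }
    add("observed_adjacency_symmetric", n_asym)
  }
  do.call(rbind, checks)
}

.stop_if_invalid <- function(bundle, context = "bundle") {
  rep <- validate_bundle(bundle)
  bad <- rep[!rep$pass, , drop = FALSE]
  if (nrow(bad) > 0)
    stop(sprintf("%s failed validation: %s", context,
                 paste(sprintf("%s (%d offenders)", bad$check, bad$n_offenders),
                       collapse = ", ")))
  invisible(bundle)
}

#' Slice a bundle into sliding windows
#'
#' Training and imputation operate on contiguous windows of \code{dt} time
#' steps taken every \code{stride} steps. The number of windows is
#' \code{floor((T - dt) / stride) + 1}; with \code{stride <= dt} the windows
#' jointly cover every time step whenever \code{(T - dt)} is a multiple of
#' \code{stride}.
#'
#' @param bundle an \code{nts_bundle}.
#' @param dt window length, \code{1 <= dt <= T}.
#' @param stride positive step between window starts.
#' @return list of \code{nts_window} objects (bundles carrying a
#'   \code{start} attribute, 0-based).
#' @export
make_windows <- function(bundle, dt, stride = dt) {
  d <- nts_dim(bundle)
  if (dt < 1 || stride < 1) stop("dt and stride must be positive")
  if (dt > d[1]) stop(sprintf("window length dt=%d exceeds T=%d", dt, d[1]))
  starts <- seq.int(0L, by = stride, length.out = (d[1] - dt) %/% stride + 1L)
  lapply(starts, function(s) window_slice(bundle, s, dt))
}

#' Extract one window from a bundle
#' @param bundle an \code{nts_bundle}.
#' @param start 0-based start index.
#' @param dt window length.
#' @return an \code{nts_window}.
#' @export
window_slice <- function(bundle, start, dt) {
  d <- nts_dim(bundle)
  if (start < 0 || start + dt > d[1]) stop("window out of range")
  idx <- seq.int(start + 1L, start + dt)
  w <- nts_bundle(
    features = bundle$features[idx, , , drop = FALSE],
    adjacency = bundle$adjacency[idx, , , drop = FALSE],
    feature_mask = bundle$feature_mask[idx, , , drop = FALSE],
    edge_mask = bundle$edge_mask[idx, , , drop = FALSE],
    timestamps = bundle$timestamps[idx],
    node_ids = bundle$node_ids, feature_names = bundle$feature_names,
    undirected = bundle$undirected, absent_edge = bundle$absent_edge)
  w$start <- as.integer(start)
  class(w) <- c("nts_window", "nts_bundle")
  w
}

## ---- file I/O -------------------------------------------------------------

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write an NTS bundle to a directory
#'
#' Layout: \code{manifest.json} (dimensions, node ids, feature names,
#' undirected flag, absent-edge rule), \code{timestamps.csv},
#' \code{features.csv} (t, node, feature, value; observed entries only),
#' \code{feature_mask.csv} (rows for mask-0 entries), \code{edges.csv}
#' (t, u, v, weight; observed nonzero edges, upper triangle only when
#' undirected), \code{edge_mask.csv} (rows whose mask differs from the
#' absent-edge default). Numeric values are written with 17 significant
#' digits so the save/load round trip is exact for doubles.
#'
#' @param bundle an \code{nts_bundle}.
#' @param path directory to create/write into.
#' @return \code{path}, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- nts_dim(bundle)
  manifest <- list(T = unname(d[1]), N = unname(d[2]), D = unname(d[3]),
                   node_ids = bundle$node_ids,
                   feature_names = bundle$feature_names,
                   undirected = bundle$undirected,
                   absent_edge = bundle$absent_edge,
                   format = "ntsimpute-bundle-v1")
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(
    data.frame(t = seq_len(d[1]) - 1L, timestamp = .fmt_num(bundle$timestamps)),
    file.path(path, "timestamps.csv"), row.names = FALSE, quote = FALSE)

  fobs <- which(bundle$feature_mask == 1, arr.ind = TRUE)
  utils::write.csv(
    data.frame(t = fobs[, 1] - 1L,
               node = bundle$node_ids[fobs[, 2]],
               feature = bundle$feature_names[fobs[, 3]],
               value = .fmt_num(bundle$features[fobs])),
    file.path(path, "features.csv"), row.names = FALSE, quote = FALSE)
  fmis <- which(bundle$feature_mask == 0, arr.ind = TRUE)
  utils::write.csv(
    data.frame(t = fmis[, 1] - 1L,
               node = bundle$node_ids[fmis[, 2]],
               feature = bundle$feature_names[fmis[, 3]],
               mask = rep(0L, nrow(fmis))),
    file.path(path, "feature_mask.csv"), row.names = FALSE, quote = FALSE)

  em <- bundle$edge_mask; a <- bundle$adjacency
  keep_pair <- function(u, v) !bundle$undirected | u < v
  eobs <- which(em == 1 & is.finite(a) & a != 0, arr.ind = TRUE)
  if (nrow(eobs)) eobs <- eobs[keep_pair(eobs[, 2], eobs[, 3]), , drop = FALSE]
  utils::write.csv(
    data.frame(t = eobs[, 1] - 1L,
               u = bundle$node_ids[eobs[, 2]],
               v = bundle$node_ids[eobs[, 3]],
               weight = .fmt_num(a[eobs])),
    file.path(path, "edges.csv"), row.names = FALSE, quote = FALSE)
  default_mask <- if (bundle$absent_edge == "zero") 1 else 0
  enod <- which(em != default_mask, arr.ind = TRUE)
  # the diagonal is never an edge slot; skip it to keep the list small
  if (nrow(enod)) enod <- enod[enod[, 2] != enod[, 3], , drop = FALSE]
  if (nrow(enod)) enod <- enod[keep_pair(enod[, 2], enod[, 3]), , drop = FALSE]
  utils::write.csv(
    data.frame(t = enod[, 1] - 1L,
               u = bundle$node_ids[enod[, 2]],
               v = bundle$node_ids[enod[, 3]],
               mask = em[enod]),
    file.path(path, "edge_mask.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
}

#' Read an NTS bundle from a directory written by \code{save_bundle}
#'
#' Feature entries absent from \code{features.csv} are missing (mask 0).
#' Edge pairs absent from \code{edges.csv} follow the manifest's absent-edge
#' rule: \code{"zero"} records them as observed weight 0, \code{"missing"}
#' as mask 0; \code{edge_mask.csv} overrides individual entries. Undirected
#' bundles store each edge once and are mirrored on load. The loaded bundle
#' is validated and malformed input raises an error naming the problem.
#'
#' @param path bundle directory.
#' @return an \code{nts_bundle}.
#' @export
load_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("manifest.json not found in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (field in c("T", "N", "D", "node_ids", "feature_names",
                  "undirected", "absent_edge")) {
    if (is.null(manifest[[field]]))
      stop("malformed manifest: missing field '", field, "'")
  }
  dT <- manifest$T; dN <- manifest$N; dD <- manifest$D
  node_ids <- as.character(manifest$node_ids)
  feature_names <- as.character(manifest$feature_names)
  if (length(node_ids) != dN)
    stop("malformed manifest: node_ids length disagrees with field 'N'")
  if (length(feature_names) != dD)
    stop("malformed manifest: feature_names length disagrees with field 'D'")

  ts <- .read_csv(file.path(path, "timestamps.csv"))
  if (nrow(ts) != dT) stop("timestamps.csv row count disagrees with manifest T")
  timestamps <- as.numeric(ts$timestamp[order(ts$t)])

  x <- array(NA_real_, c(dT, dN, dD))
  fm <- array(0, c(dT, dN, dD))
  fe <- .read_csv(file.path(path, "features.csv"))
  if (nrow(fe)) {
    ti <- fe$t + 1L
    ni <- match(fe$node, node_ids)
    di <- match(fe$feature, feature_names)
    if (anyNA(ni) || anyNA(di) || any(ti < 1 | ti > dT))
      stop("features.csv refers to unknown t, node or feature")
    idx <- cbind(ti, ni, di)
    x[idx] <- as.numeric(fe$value)
    fm[idx] <- 1
  }

  a <- array(if (manifest$absent_edge == "zero") 0 else NA_real_, c(dT, dN, dN))
  em <- array(if (manifest$absent_edge == "zero") 1 else 0, c(dT, dN, dN))
  ed <- .read_csv(file.path(path, "edges.csv"))
  if (nrow(ed)) {
    ti <- ed$t + 1L
    ui <- match(ed$u, node_ids)
    vi <- match(ed$v, node_ids)
    if (anyNA(ui) || anyNA(vi) || any(ti < 1 | ti > dT))
      stop("edges.csv refers to unknown t or node")
    w <- as.numeric(ed$weight)
    if (any(is.finite(w) & w < 0)) stop("edges.csv contains negative weights")
    a[cbind(ti, ui, vi)] <- w
    em[cbind(ti, ui, vi)] <- 1
    if (manifest$undirected) {
      a[cbind(ti, vi, ui)] <- w
      em[cbind(ti, vi, ui)] <- 1
    }
  }
  emf <- .read_csv(file.path(path, "edge_mask.csv"))
  if (nrow(emf)) {
    ti <- emf$t + 1L
    ui <- match(emf$u, node_ids)
    vi <- match(emf$v, node_ids)
    if (anyNA(ui) || anyNA(vi)) stop("edge_mask.csv refers to unknown node")
    em[cbind(ti, ui, vi)] <- emf$mask
    if (manifest$undirected) em[cbind(ti, vi, ui)] <- emf$mask
    masked0 <- emf$mask == 0
    a[cbind(ti, ui, vi)[masked0, , drop = FALSE]] <- NA_real_
    if (manifest$undirected)
      a[cbind(ti, vi, ui)[masked0, , drop = FALSE]] <- NA_real_
  }
  # the diagonal is structurally zero and observed
  for (t in seq_len(dT)) { diag(a[t, , ]) <- 0; diag(em[t, , ]) <- 1 }

  b <- nts_bundle(x, a, fm, em, timestamps, node_ids, feature_names,
                  undirected = isTRUE(manifest$undirected),
                  absent_edge = manifest$absent_edge)
  .stop_if_invalid(b, paste0("bundle at ", path))
  b
}

.same_shape <- function(a, b) {
  identical(unname(dim(as.array(a))), unname(dim(as.array(b))))
}

# Features with masked-out entries replaced by zero; safe to feed to linear
# algebra (NaN sentinels must never propagate).
.clean_features <- function(bundle) {
  x <- bundle$features
  x[bundle$feature_mask == 0] <- 0
  x[!is.finite(x)] <- 0
  x
}

# Observed adjacency with masked-out and non-finite entries as weight 0.
.observed_adjacency <- function(bundle, t) {
  at <- bundle$adjacency[t, , ]
  at[bundle$edge_mask[t, , ] == 0] <- 0
  at[!is.finite(at)] <- 0
  at
}
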