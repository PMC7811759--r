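#' Convert edge weights to path lengths
#'
#' Path-based measures (local efficiency, betweenness) run on lengths
#' L_ij = 1 / w_ij; absent edges (w = 0) have infinite length. This is the
#' Brain-Connectivity-Toolbox convention for connection-strength weights.
#'
#' @param w Nonnegative symmetric weight matrix.
#' @return Matrix of lengths; `Inf` where no edge exists, 0 on the diagonal.
#' @export
weight_to_length <- function(w) {
  stopifnot(is.matrix(w), !anyNA(w), all(w >= 0))
  l <- ifelse(w > 0, 1 / w, Inf)
  diag(l) <- 0
  l
}

# weights scaled to [0, 1] by the matrix maximum; all-zero matrix passes through
scale_by_max <- function(w) {
  mx <- max(w)
  if (mx > 0) w / mx else w
}

#' Weighted clustering coefficient
#'
#' Onnela-style geometric-mean triangle intensity on weights scaled by the
#' matrix maximum: CC_i = sum_(j,h) (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1)),
#' the weighted form used by the Brain Connectivity Toolbox. Nodes with
#' degree < 2 get 0.
#'
#' @param x A `hemi_connectome` or a nonnegative symmetric matrix.
#' @return Named numeric vector of per-node values in \[0, 1\].
#' @export
clustering_coefficient <- function(x) {
  w <- as_weight_matrix(x)
  ws <- scale_by_max(w) ^ (1 / 3)
  cyc <- diag(ws %*% ws %*% ws)        # twice the triangle intensity per node
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  names(cc) <- rownames(w)
  cc
}

#' Weighted local efficiency
#'
#' For each node i, the efficiency of the subgraph induced on i's
#' neighbours: the mean over neighbour pairs (j, h) of 1 / d_jh, where d is
#' the shortest-path length within the induced subgraph on lengths 1 / w'
#' (weights scaled by the matrix maximum, so d >= 1 and LE is in \[0, 1\]).
#' Nodes with degree < 2 get 0.
#'
#' @inheritParams clustering_coefficient
#' @return Named numeric vector of per-node values in \[0, 1\].
#' @export
local_efficiency <- function(x) {
  w <- as_weight_matrix(x)
  le <- local_efficiency_cpp(w)
  names(le) <- rownames(w)
  le
}

#' Weighted betweenness centrality
#'
#' Brandes betweenness on lengths 1 / w, with fractional credit for tied
#' shortest paths, counted over unordered pairs excluding the node itself
#' and reported unnormalized by default.
#'
#' @inheritParams clustering_coefficient
#' @param normalize If TRUE, multiply by 2 / ((n - 1)(n - 2)).
#' @return Named numeric vector; NA for isolated nodes (the quantity is
#'   undefined when no path can touch the node).
#' @export
betweenness_centrality <- function(x, normalize = FALSE) {
  w <- as_weight_matrix(x)
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  g <- igraph::make_graph(rbind(ut[, 1], ut[, 2]), n = n, directed = FALSE)
  bc <- igraph::betweenness(g, directed = FALSE, weights = 1 / w[ut])
  if (normalize) bc <- bc * 2 / ((n - 1) * (n - 2))
  bc[rowSums(w > 0) == 0] <- NA_real_
  names(bc) <- rownames(w)
  bc
}

#' Eigenvector centrality
#'
#' Entrywise-nonnegative principal eigenvector of the weight matrix, scaled
#' to unit Euclidean norm, computed by power iteration on the full matrix
#' (disconnected components allowed; mass concentrates on the dominant
#' component).
#'
#' @inheritParams clustering_coefficient
#' @param max_iter,tol Iteration budget and convergence tolerance on the
#'   iterate difference.
#' @return Named numeric vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(x, max_iter = 1000L, tol = 1e-12) {
  w <- as_weight_matrix(x)
  n <- nrow(w)
  if (max(w) == 0) {
    v <- rep(NA_real_, n)
    names(v) <- rownames(w)
    return(v)
  }
  # spectral shift breaks the +/- lambda tie on bipartite graphs without
  # changing eigenvectors
  shift <- max(rowSums(w))
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    u <- as.vector(w %*% v) + shift * v
    nu <- sqrt(sum(u^2))
    if (nu == 0) stop("eigenvector iteration collapsed to zero")
    u <- u / nu
    if (max(abs(u - v)) < tol) {
      v <- u
      names(v) <- rownames(w)
      return(abs(v))
    }
    v <- u
  }
  stop(sprintf("eigenvector centrality did not converge in %d iterations (residual %.3e)",
               max_iter, max(abs(as.vector(w %*% v) / sqrt(sum((w %*% v)^2)) - v))))
}

as_weight_matrix <- function(x) {
  if (inherits(x, "hemi_connectome")) return(x$matrix)
  stopifnot(is.matrix(x), nrow(x) == ncol(x), !anyNA(x), all(x >= 0),
            max(abs(x - t(x))) < 1e-8)
  if (is.null(rownames(x))) rownames(x) <- colnames(x) <- paste0("n", seq_len(nrow(x)))
  x
}

#' Compute all nodal measures for a cohort
#'
#' One row per (subject, role, weight kind, node) with the four weighted
#' nodal measures. Deterministic given the inputs.
#'
#' @param cohort A `glioma_cohort` (see [generate_cohort()]) or any list with
#'   `subjects` (data.frame with case_id) and `connectomes\[\[case_id\]\]\[\[role\]\]\[\[kind\]\]`
#'   weight matrices.
#' @return data.frame with columns case_id, role, weight_kind, node, cc, le,
#'   bc, ec.
#' @export
compute_nodal_metrics <- function(cohort) {
  roles <- c("ipsilesional", "contralesional")
  kinds <- c("count", "FA", "MD")
  out <- vector("list", nrow(cohort$subjects) * length(roles) * length(kinds))
  i <- 0L
  for (cid in cohort$subjects$case_id) {
    for (role in roles) {
      for (kind in kinds) {
        w <- cohort$connectomes[[cid]][[role]][[kind]]
        if (is.null(w)) {
          stop("missing matrix for subject ", cid, ", ", role, ", ", kind)
        }
        i <- i + 1L
        out[[i]] <- data.frame(
          case_id = cid, role = role, weight_kind = kind,
          node = rownames(w),
          cc = clustering_coefficient(w),
          le = local_efficiency(w),
          bc = betweenness_centrality(w),
          ec = eigenvector_centrality(w),
          row.names = NULL
        )
      }
    }
  }
  do.call(rbind, out)
}
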