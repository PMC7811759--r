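# Brute-force oracles for the weighted nodal measures, independent of the
# package implementation: exhaustive simple-path enumeration for shortest
# paths, direct triangle sums for clustering. Only feasible for <= ~7 nodes.

# all simple paths from s to t as lists of node indices
enumerate_paths <- function(adj, s, t) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (nxt in which(adj[last, ] > 0)) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(s)
  out
}

path_cost <- function(lengths, path) {
  if (length(path) < 2) return(0)
  sum(lengths[cbind(path[-length(path)], path[-1])])
}

# shortest-path distances by exhaustive enumeration on a length matrix
oracle_distances <- function(lengths) {
  adj <- is.finite(lengths) & lengths > 0
  n <- nrow(lengths)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- enumerate_paths(adj, s, t)
    if (length(ps)) d[s, t] <- d[t, s] <- min(vapply(ps, path_cost,
                                                    1, lengths = lengths))
  }
  d
}

oracle_cc <- function(w) {
  n <- nrow(w)
  ws <- if (max(w) > 0) w / max(w) else w
  sapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    s <- 0
    for (j in nb) for (h in nb) {
      if (j != h && w[j, h] > 0) s <- s + (ws[i, j] * ws[i, h] * ws[j, h])^(1 / 3)
    }
    s / (k * (k - 1))
  })
}

oracle_le <- function(w) {
  n <- nrow(w)
  ws <- if (max(w) > 0) w / max(w) else w
  sapply(seq_len(n), function(i) {
    nb <- which(ws[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- ws[nb, nb, drop = FALSE]
    lengths <- ifelse(sub > 0, 1 / sub, Inf)
    d <- oracle_distances(lengths)
    inv <- 1 / d
    diag(inv) <- 0
    sum(inv[is.finite(inv)]) / (k * (k - 1))
  })
}

oracle_bc <- function(w) {
  n <- nrow(w)
  lengths <- ifelse(w > 0, 1 / w, Inf)
  adj <- w > 0
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- enumerate_paths(adj, s, t)
    if (!length(ps)) next
    costs <- vapply(ps, path_cost, 1, lengths = lengths)
    best <- min(costs)
    sp <- ps[costs <= best + 1e-12]
    for (p in sp) {
      mid <- setdiff(p, c(s, t))
      bc[mid] <- bc[mid] + 1 / length(sp)
    }
  }
  bc[rowSums(w > 0) == 0] <- NA_real_
  bc
}

# random connected symmetric weighted graph on n nodes
random_weighted_graph <- function(n, p = 0.6) {
  repeat {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    on <- stats::runif(length(ut)) < p
    w[ut[on]] <- stats::runif(sum(on), 0.2, 3)
    w <- w + t(w)
    reach <- (diag(n) + (w > 0))
    for (i in seq_len(n)) reach <- reach %*% reach
    if (all(reach > 0)) return(w)
  }
}

# small synthetic cohort for pipeline-level tests
tiny_cohort <- function(n = 4, seed = 7, lobe = "frontal", ...) {
  cfg <- generator_config(n_subjects = n, seed = seed)
  generate_cohort(cfg, lesion_model(lobe, ...))
}
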