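#' Percent change of a nodal measure between hemispheres
#'
#' Implemented exactly as the defining formula prints:
#' 100 * (contralesional - ipsilesional) / ipsilesional. Note the
#' ipsilesional denominator: with this convention an ipsilesional increase
#' yields a negative percent change. `direction = "ipsi_vs_contra"` flips to
#' the conversational convention 100 * (ipsi - contra) / contra.
#'
#' @param contra,ipsi Numeric vectors (recycled as usual).
#' @param direction "contra_vs_ipsi" (default, the printed formula) or
#'   "ipsi_vs_contra".
#' @return Percent change; NA when the denominator is 0 or either input NA.
#' @export
percent_change <- function(contra, ipsi,
                           direction = c("contra_vs_ipsi", "ipsi_vs_contra")) {
  direction <- match.arg(direction)
  if (direction == "contra_vs_ipsi") {
    out <- 100 * (contra - ipsi) / ipsi
    out[!is.na(ipsi) & ipsi == 0] <- NA_real_
  } else {
    out <- 100 * (ipsi - contra) / contra
    out[!is.na(contra) & contra == 0] <- NA_real_
  }
  out
}

#' Mean percent change across the three weightings
#'
#' Arithmetic mean of the count, FA and MD percent changes; NA if any
#' component is NA.
#'
#' @param pct_count,pct_fa,pct_md Numeric vectors.
#' @return (pct_count + pct_fa + pct_md) / 3.
#' @export
mean_percent_change <- function(pct_count, pct_fa, pct_md) {
  (pct_count + pct_fa + pct_md) / 3
}

#' Per-node percent-change table
#'
#' Group-level percent change: nodal measures are first averaged over
#' subjects per (node, role, weight kind), the percent change is taken on
#' those group means, and the mean percent change across the three weight
#' kinds is appended. `level = "subject"` instead returns one row per
#' (subject, node, metric).
#'
#' @param metrics data.frame from [compute_nodal_metrics()].
#' @param level "group" (default) or "subject".
#' @inheritParams percent_change
#' @return data.frame with columns (case_id if subject-level), node, metric,
#'   pct_count, pct_fa, pct_md, mean_pct.
#' @export
percent_change_table <- function(metrics, level = c("group", "subject"),
                                 direction = c("contra_vs_ipsi",
                                               "ipsi_vs_contra")) {
  level <- match.arg(level)
  direction <- match.arg(direction)
  meas <- c("cc", "le", "bc", "ec")
  long <- do.call(rbind, lapply(meas, function(ms) {
    data.frame(case_id = metrics$case_id, role = metrics$role,
               weight_kind = metrics$weight_kind, node = metrics$node,
               metric = ms, value = metrics[[ms]])
  }))
  if (level == "group") {
    agg <- stats::aggregate(value ~ role + weight_kind + node + metric,
                            data = long, FUN = mean, na.action = stats::na.pass)
    agg$case_id <- "group"
    long <- agg
  }
  wide <- stats::reshape(long, direction = "wide",
                         idvar = c("case_id", "weight_kind", "node", "metric"),
                         timevar = "role")
  pct <- percent_change(wide$value.contralesional, wide$value.ipsilesional,
                        direction = direction)
  wide$pct <- pct
  out <- stats::reshape(wide[, c("case_id", "node", "metric", "weight_kind",
                                 "pct")],
                        direction = "wide", idvar = c("case_id", "node",
                                                      "metric"),
                        timevar = "weight_kind")
  names(out)[names(out) == "pct.count"] <- "pct_count"
  names(out)[names(out) == "pct.FA"] <- "pct_fa"
  names(out)[names(out) == "pct.MD"] <- "pct_md"
  out$mean_pct <- mean_percent_change(out$pct_count, out$pct_fa, out$pct_md)
  rownames(out) <- NULL
  if (level == "group") out$case_id <- NULL
  out
}

#' Per-node impact score
#'
#' Collapses a group-level percent-change table to one score per node: the
#' mean over the four measures of |mean percent change|. Magnitude is used
#' because "highly impacted" nodes are those whose measures moved most in
#' either direction. NA components propagate.
#'
#' @param pct_table Group-level table from [percent_change_table()].
#' @return Named numeric vector over nodes.
#' @export
node_impact_scores <- function(pct_table) {
  s <- tapply(abs(pct_table$mean_pct), pct_table$node, mean)
  s[atlas_labels()[atlas_labels() %in% names(s)]]
}

#' Top-ten-percentile node selection
#'
#' Nearest-rank 90th percentile: the threshold is the value at rank
#' ceiling(0.9 n) of the ascending sort (NAs ranked last, i.e. lowest);
#' every node at or above the threshold is returned, so ties at the
#' threshold all enter the set. Over 56 distinct values this returns exactly
#' 6 nodes.
#'
#' @param scores Named numeric vector, one value per node.
#' @param group Optional lesion-group tag stored on the result.
#' @return List of class `top_decile_set` with `nodes`, `threshold`, `group`.
#' @export
top_decile_nodes <- function(scores, group = NA_character_) {
  if (all(is.na(scores))) stop("all node scores are NA")
  v <- scores
  v[is.na(v)] <- -Inf
  n <- length(v)
  thr <- unname(sort(v)[ceiling(0.9 * n)])
  nodes <- names(v)[v >= thr]
  if (length(nodes) == n) {
    warning("all nodes tie at the top-decile threshold")
  }
  structure(list(nodes = nodes, threshold = thr, group = group),
            class = "top_decile_set")
}

#' Dunn's post hoc pairwise rank test
#'
#' Standard Dunn z statistics on the joint ranks with tie correction;
#' p-values are two-sided and reported unadjusted.
#'
#' @param values Numeric vector.
#' @param groups Factor/character vector of the same length.
#' @return data.frame with columns group_a, group_b, z, p_value.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  lev <- levels(groups)
  cmb <- utils::combn(lev, 2)
  z <- apply(cmb, 2, function(g) {
    (rbar[g[1]] - rbar[g[2]]) /
      sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[g[1]] + 1 / ni[g[2]]))
  })
  data.frame(group_a = cmb[1, ], group_b = cmb[2, ], z = as.numeric(z),
             p_value = 2 * stats::pnorm(-abs(as.numeric(z))))
}

#' Lobar distribution test of top-decile percent changes
#'
#' Kruskal-Wallis H-test (with tie correction) across the three top-decile
#' node sets' percent-change values within one lesion group and one
#' measure; Dunn pairwise comparisons are run only when the H-test p-value
#' is below `alpha` and are reported unadjusted.
#'
#' @param groups Named list of numeric vectors (typically frontal, parietal,
#'   temporal top-decile sets), each with at least 2 values.
#' @param alpha Gate for the post hoc stage.
#' @return List of class `lobar_test` with `h`, `p_value`, `dunn` (data.frame
#'   or NULL).
#' @export
lobar_distribution_test <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("every group needs at least 2 values")
  }
  values <- unlist(groups, use.names = FALSE)
  lab <- factor(rep(names(groups), vapply(groups, length, 1L)),
                levels = names(groups))
  kw <- stats::kruskal.test(values, lab)
  dunn <- NULL
  if (!is.nan(kw$p.value) && kw$p.value < alpha) {
    dunn <- dunn_test(values, lab)
  }
  structure(list(h = unname(kw$statistic), p_value = kw$p.value, dunn = dunn),
            class = "lobar_test")
}

#' Pearson correlation of tumour volume with mean percent change
#'
#' @param mean_pct Per-subject mean percent change across all measures.
#' @param volumes Tumour volumes, same length (n >= 3).
#' @return List with `r`, `p_value`, `n`; NA with a warning on zero variance.
#' @export
correlate_volume <- function(mean_pct, volumes) {
  stopifnot(length(mean_pct) == length(volumes))
  keep <- is.finite(mean_pct) & is.finite(volumes)
  x <- mean_pct[keep]; y <- volumes[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Pearson correlation of nodal percent change with distance from the tumour
#'
#' Distance is the Euclidean norm between each node centroid and the tumour
#' centroid; one correlation per (measure, weight kind) against the per-node
#' percent change.
#'
#' @param pct_table Group-level table from [percent_change_table()].
#' @param tumour_centroid 3-vector (mm).
#' @param centroids 56 x 3 node-centroid matrix (defaults to the packaged
#'   atlas, left hemisphere).
#' @return data.frame with columns metric, weight_kind, r, p_value, n.
#' @export
correlate_distance <- function(pct_table, tumour_centroid, centroids = NULL) {
  if (is.null(centroids)) centroids <- node_centroids("L")
  stopifnot(length(tumour_centroid) == 3)
  d <- sqrt(rowSums(sweep(centroids, 2, tumour_centroid)^2))
  kinds <- c(pct_count = "count", pct_fa = "FA", pct_md = "MD")
  rows <- list()
  for (ms in unique(pct_table$metric)) {
    sub <- pct_table[pct_table$metric == ms, ]
    dist <- d[match(sub$node, rownames(centroids))]
    if (anyNA(dist)) stop("missing centroids for some nodes")
    for (col in names(kinds)) {
      keep <- is.finite(sub[[col]]) & is.finite(dist)
      r <- p <- NA_real_
      if (sum(keep) >= 3 && stats::sd(sub[[col]][keep]) > 0 &&
          stats::sd(dist[keep]) > 0) {
        ct <- stats::cor.test(sub[[col]][keep], dist[keep])
        r <- unname(ct$estimate); p <- ct$p.value
      } else {
        warning("degenerate input for ", ms, "/", kinds[[col]],
                "; correlation undefined")
      }
      rows[[paste(ms, col)]] <- data.frame(metric = ms,
                                           weight_kind = kinds[[col]],
                                           r = r, p_value = p, n = sum(keep))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
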