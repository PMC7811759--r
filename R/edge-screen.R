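#' Contralesional confidence-interval screen on end-point tract count
#'
#' For every edge present in the cohort, the contralesional per-subject
#' weights give a mean and a two-sided t confidence interval
#' (mean +/- t_(1-(1-level)/2, n-1) * SD / sqrt(n)); the ipsilesional mean is
#' flagged "increased" if it exceeds the upper bound, "decreased" below the
#' lower bound, "ns" inside. This mirrors the published screening procedure:
#' it compares one group mean against the CI of another and is a screening
#' heuristic, not a calibrated two-sample test. Edges with zero weight in
#' every subject on both sides are skipped; edges absent in some subjects
#' contribute their zeros to the means. A zero-variance contralesional edge
#' yields a point interval, so any difference is flagged.
#'
#' @param cohort A `glioma_cohort` (needs >= 3 subjects).
#' @param level Confidence level (default 0.95).
#' @return data.frame of class `edge_screen`: node_a, node_b, n_subjects,
#'   contra_mean, ci_lower, ci_upper, ipsi_mean, significance, mean_change
#'   (ipsi - contra, NA for "ns" edges).
#' @export
edge_ci_screen <- function(cohort, level = 0.95) {
  n <- nrow(cohort$subjects)
  if (n < 3) stop("edge screen needs at least 3 subjects, got ", n)
  stopifnot(level > 0, level < 1)
  stk <- edge_stack(cohort, "count")
  keep <- rowSums(stk$ipsi) + rowSums(stk$contra) > 0
  ci <- edge_ci(stk$contra[keep, , drop = FALSE], level)
  ipsi_mean <- rowMeans(stk$ipsi[keep, , drop = FALSE])
  sig <- ifelse(ipsi_mean > ci$upper, "increased",
                ifelse(ipsi_mean < ci$lower, "decreased", "ns"))
  out <- data.frame(node_a = stk$pairs[keep, 1], node_b = stk$pairs[keep, 2],
                    n_subjects = n, contra_mean = ci$mean,
                    ci_lower = ci$lower, ci_upper = ci$upper,
                    ipsi_mean = ipsi_mean, significance = sig,
                    mean_change = ifelse(sig == "ns", NA_real_,
                                         ipsi_mean - ci$mean))
  class(out) <- c("edge_screen", class(out))
  out
}

# per-edge subject stacks: rows = upper-triangle edges, cols = subjects
edge_stack <- function(cohort, kind) {
  labels <- cohort$labels
  ut <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  get <- function(role) {
    vapply(cohort$subjects$case_id, function(cid) {
      m <- cohort$connectomes[[cid]][[role]][[kind]]
      if (is.null(m)) stop("missing matrix for subject ", cid, ", ", role,
                           ", ", kind)
      m[ut]
    }, numeric(nrow(ut)))
  }
  list(pairs = cbind(labels[ut[, 1]], labels[ut[, 2]]),
       ipsi = get("ipsilesional"), contra = get("contralesional"))
}

edge_ci <- function(values, level) {
  n <- ncol(values)
  mu <- rowMeans(values)
  sd <- apply(values, 1, stats::sd)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  half <- tq * sd / sqrt(n)
  list(mean = mu, lower = mu - half, upper = mu + half)
}

#' FA/MD follow-up on count-significant edges
#'
#' Applies the same contralesional-CI construction to FA and then MD,
#' restricted to edges the count screen flagged; each is classified
#' increased/decreased/ns independently. Edges the count screen did not flag
#' never acquire follow-up values.
#'
#' @param screen Result of [edge_ci_screen()].
#' @param cohort The same `glioma_cohort`.
#' @param level Confidence level (default 0.95).
#' @param drop_absent If TRUE (default), subjects in which an edge is absent
#'   (zero in both hemispheres) are excluded from that edge's FA/MD means
#'   and CI: the diffusion value of a missing connection is undefined, not
#'   zero. Set FALSE to keep the raw matrix semantics of the count screen.
#' @return The screen with columns fa_contra, fa_ipsi, fa_sig, md_contra,
#'   md_ipsi, md_sig added (count-ns rows stay NA under the restriction
#'   rule).
#' @export
diffusion_followup <- function(screen, cohort, level = 0.95,
                               drop_absent = TRUE) {
  stopifnot(inherits(screen, "edge_screen"))
  on <- screen$significance != "ns"
  for (kind in c("FA", "MD")) {
    stk <- edge_stack(cohort, kind)
    key <- paste(stk$pairs[, 1], stk$pairs[, 2])
    idx <- match(paste(screen$node_a, screen$node_b), key)
    if (anyNA(idx)) stop(kind, " matrices missing edges present in the screen")
    mu_c <- mu_i <- rep(NA_real_, nrow(screen))
    sig <- rep(NA_character_, nrow(screen))
    for (r in which(on)) {
      contra <- stk$contra[idx[r], ]
      ipsi <- stk$ipsi[idx[r], ]
      if (drop_absent) {
        keep <- contra > 0 | ipsi > 0
        contra <- contra[keep]; ipsi <- ipsi[keep]
      }
      if (length(contra) < 3) next
      n <- length(contra)
      tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
      half <- tq * stats::sd(contra) / sqrt(n)
      mu_c[r] <- mean(contra)
      mu_i[r] <- mean(ipsi)
      sig[r] <- if (mu_i[r] > mu_c[r] + half) "increased"
                else if (mu_i[r] < mu_c[r] - half) "decreased" else "ns"
    }
    pre <- tolower(kind)
    screen[[paste0(pre, "_contra")]] <- mu_c
    screen[[paste0(pre, "_ipsi")]] <- mu_i
    screen[[paste0(pre, "_sig")]] <- sig
  }
  screen
}

#' Lobe composition of screened connections
#'
#' Collects the unique end-point regions over edges flagged in the given
#' direction and tabulates them per lobe; the percentage denominator is the
#' number of unique regions, and percentages are rounded to the nearest
#' integer.
#'
#' @param edges data.frame with columns node_a, node_b and a direction
#'   column: either an `edge_screen` (column `significance`) or a published
#'   connection table from [read_edge_table()] (column `direction`).
#' @param direction "increased" or "decreased".
#' @return List of class `lobe_composition`: `direction`, `regions` (unique
#'   end points), `table` (lobe, count, pct), `denominator`.
#' @export
lobe_composition <- function(edges, direction = c("increased", "decreased")) {
  direction <- match.arg(direction)
  dcol <- if ("significance" %in% names(edges)) "significance" else "direction"
  sel <- edges[edges[[dcol]] == direction, , drop = FALSE]
  regions <- unique(c(sel$node_a, sel$node_b))
  if (length(regions) == 0) {
    return(structure(list(direction = direction, regions = character(),
                          table = data.frame(lobe = character(),
                                             count = integer(),
                                             pct = numeric()),
                          denominator = 0L),
                     class = "lobe_composition"))
  }
  lb <- lobe_of(regions)
  tab <- as.data.frame(table(lobe = lb), stringsAsFactors = FALSE)
  names(tab)[2] <- "count"
  tab$pct <- round_half_up(100 * tab$count / length(regions))
  structure(list(direction = direction, regions = sort(regions), table = tab,
                 denominator = length(regions)),
            class = "lobe_composition")
}

#' @export
print.lobe_composition <- function(x, ...) {
  cat(sprintf("Connections with %s end-point tract count: %d unique regions\n",
              x$direction, x$denominator))
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %s: %d/%d (%d%%)\n", x$table$lobe[i], x$table$count[i],
                x$denominator, x$table$pct[i]))
  }
  invisible(x)
}

#' Plot a screened edge set as a 2-D node-edge diagram
#'
#' Simple planar rendering of the significant edges at the atlas centroids
#' (x-y plane), colour-coded by direction.
#'
#' @param screen An `edge_screen` or published connection table.
#' @param centroids Node-centroid matrix (defaults to the packaged atlas).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_edge_screen <- function(screen, centroids = NULL, ...) {
  if (is.null(centroids)) centroids <- node_centroids("L")
  dcol <- if ("significance" %in% names(screen)) "significance" else "direction"
  sel <- screen[screen[[dcol]] %in% c("increased", "decreased"), , drop = FALSE]
  graphics::plot(centroids[, "y"], centroids[, "z"], pch = 16, cex = 0.6,
                 col = "grey60", xlab = "y (mm)", ylab = "z (mm)", ...)
  for (i in seq_len(nrow(sel))) {
    a <- centroids[sel$node_a[i], c("y", "z")]
    b <- centroids[sel$node_b[i], c("y", "z")]
    graphics::segments(a[1], a[2], b[1], b[2],
                       col = if (sel[[dcol]][i] == "increased") "firebrick"
                             else "steelblue", lwd = 2)
  }
  used <- unique(c(sel$node_a, sel$node_b))
  graphics::text(centroids[used, "y"], centroids[used, "z"], used, cex = 0.6,
                 pos = 3)
  invisible(screen)
}
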