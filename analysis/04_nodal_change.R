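#!/usr/bin/env Rscript
# Highly impacted nodes: per-node percent change from the contralesional
# hemisphere under each weighting, mean percent change, top-ten-percentile
# node sets per lesion group, lobar Kruskal-Wallis/Dunn comparisons, and the
# tumour-volume / node-distance correlations.

library(hemiconn)
library(jsonlite)

cohort <- read_cohort("results/cohort")
metrics <- read.csv("results/nodal_metrics.csv")
subjects <- cohort$subjects

pct <- list(); top <- list()
for (lb in c("frontal", "parietal", "temporal")) {
  ids <- subjects$case_id[subjects$lobe == lb]
  tab <- percent_change_table(metrics[metrics$case_id %in% ids, ])
  pct[[lb]] <- tab
  top[[lb]] <- top_decile_nodes(node_impact_scores(tab), group = lb)
  write.csv(tab, sprintf("results/percent_change_%s.csv", lb),
            row.names = FALSE)
  cat(sprintf("%s lesions: top-decile nodes (threshold %.1f): %s\n", lb,
              top[[lb]]$threshold, paste(top[[lb]]$nodes, collapse = ", ")))
}
write_json(lapply(top, function(s) list(group = s$group,
                                        threshold = s$threshold,
                                        nodes = s$nodes)),
           "results/top_decile_sets.json", auto_unbox = TRUE, digits = NA)

cat("\nLobar distribution tests (per lesion group and measure):\n")
lobar <- list()
for (lb in names(pct)) {
  for (ms in c("cc", "le", "bc", "ec")) {
    sets <- lapply(top, function(s) {
      v <- pct[[lb]]$mean_pct[pct[[lb]]$metric == ms &
                                pct[[lb]]$node %in% s$nodes]
      v[is.finite(v)]
    })
    if (any(lengths(sets) < 2)) next
    lt <- lobar_distribution_test(sets)
    lobar[[paste(lb, ms)]] <- data.frame(
      lesion_group = lb, metric = ms, h = lt$h, p = lt$p_value,
      dunn = if (is.null(lt$dunn)) "" else
        paste(sprintf("%s-%s p=%.3g", lt$dunn$group_a, lt$dunn$group_b,
                      lt$dunn$p_value), collapse = "; "))
  }
}
lobar <- do.call(rbind, lobar)
write.csv(lobar, "results/lobar_tests.csv", row.names = FALSE)
print(lobar, row.names = FALSE)

# volume correlation: volumes are drawn independently of the lesion effect,
# so this is a null check, as in the original design
set.seed(20260104)
volumes <- rlnorm(nrow(subjects), meanlog = 3, sdlog = 0.6)   # cm^3 scale
subj_pct <- sapply(subjects$case_id, function(cid) {
  tab <- percent_change_table(metrics[metrics$case_id == cid, ],
                              level = "subject")
  mean(tab$mean_pct[is.finite(tab$mean_pct)])
})
cv <- correlate_volume(subj_pct, volumes)
cat(sprintf("\nTumour volume vs mean %%change: r = %.3f, p = %.3f (n = %d)\n",
            cv$r, cv$p_value, cv$n))

# distance correlations for the frontal group against its lesion centroid
frontal_centroid <- lesion_model("frontal")$centroid
dist_cor <- correlate_distance(pct$frontal, frontal_centroid)
write.csv(dist_cor, "results/distance_correlations.csv", row.names = FALSE)
cat("\nNode distance vs %change (frontal group):\n")
print(dist_cor, digits = 3, row.names = FALSE)
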