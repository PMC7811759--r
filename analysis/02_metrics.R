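#!/usr/bin/env Rscript
# Compute the four weighted nodal measures (CC, LE, BC, EC) for every
# hemisphere and weighting of the simulated cohort.

library(hemiconn)

cohort <- read_cohort("results/cohort")
metrics <- compute_nodal_metrics(cohort)
dir.create("results", showWarnings = FALSE)
write.csv(metrics, "results/nodal_metrics.csv", row.names = FALSE)

cat("Nodal metric table:", nrow(metrics), "rows",
    "(", nrow(cohort$subjects), "subjects x 2 roles x 3 weights x 56 nodes )\n")
agg <- aggregate(cbind(cc, le, bc, ec) ~ role + weight_kind, data = metrics,
                 FUN = function(x) round(mean(x, na.rm = TRUE), 4))
print(agg)
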