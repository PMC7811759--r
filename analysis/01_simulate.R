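#!/usr/bin/env Rscript
# Generate the study-design synthetic cohort: 33 subjects with unilateral
# lobe-localized lesions (22 frontal, 5 parietal, 6 temporal), three weight
# kinds per hemisphere, and write it with its ground truth under
# results/cohort/.

library(hemiconn)

out <- "results/cohort"
lobes <- rep(c("frontal", "parietal", "temporal"), c(22, 5, 6))
cfg <- generator_config(n_subjects = length(lobes), seed = 20260101)
cohort <- generate_cohort(cfg, lapply(lobes, lesion_model))
write_cohort(cohort, out)

cat("Wrote", length(lobes), "subjects x 2 hemispheres x 3 weight kinds to",
    out, "\n")
print(summarize_cohort(cohort$subjects))
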