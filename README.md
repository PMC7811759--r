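# hemiconn

Hemispheric structural-network analysis of lobe-localized glioma.

Unilateral gliomas reshape the white-matter network of the hemisphere they
sit in. Because the contralesional hemisphere of the same patient is a
natural control, a paired design can ask: which network properties shift
ipsilesionally, which atlas regions are most impacted for a given lesion
lobe, and which individual connections change — and is the tissue behind
those connections degraded? `hemiconn` implements that analysis for 56-node
AAL2 hemispheric connectomes weighted by end-point streamline count,
fractional anisotropy (FA) or mean diffusivity (MD), for researchers working
with DTI tractography in neuro-oncology.

The statistical core:

- **Weighted nodal graph measures** — Onnela clustering coefficient
  `CC_i = Σ_(j,h) (ŵ_ij ŵ_ih ŵ_jh)^(1/3) / (k_i(k_i−1))` on max-scaled
  weights; local efficiency of each node's neighbour subgraph on lengths
  `1/ŵ`; Brandes betweenness on lengths `1/w`; unit-norm eigenvector
  centrality.
- **Hemispheric tests** — per (weighting × measure), log-transform, Tukey
  outlier screen, two-sample Wilcoxon rank-sum, Benjamini–Hochberg across
  the 12 tests.
- **Percent-change node statistic** —
  `%change = 100 (contra − ipsi)/ipsi` per weighting,
  `mean %change = (count + FA + MD)/3`, top-ten-percentile node sets
  (nearest-rank; 6 of 56), lobar Kruskal–Wallis with post hoc Dunn z-tests.
- **Connection screen** — per edge, the contralesional mean count across
  subjects and its 95% t-interval; ipsilesional means outside the interval
  are flagged, and flagged connections get FA/MD follow-up the same way.
- **Synthetic lesioned-connectome generator** — a seeded model of paired
  hemispheric networks (posterior-medial rich club, exponential distance
  rule, Poisson streamline counting noise) with a parameterized lesion:
  count inflation, FA depression and MD elevation decaying with distance
  from the lesion centroid. Every downstream stage is testable without
  imaging data.

## Worked example

The package bundles the demographics table of a 33-patient unilateral
glioma cohort (22 frontal, 5 parietal, 6 temporal) and the published
group-level connection screens, used as worked examples:

```r
library(hemiconn)
summarize_cohort(read_subjects())
#> Cohort: n = 33; age 45.73 (SD 16.76; range 20-80)
#> Sex: F 14 (42%), M 19 (58%)
#> Pathology: astrocytoma 7 (21%), GBM 18 (55%), oligodendroglioma 8 (24%)
#> WHO grade: 2: 9 (27%), 3: 6 (18%), 4: 18 (55%)
#> Registration R^2: 0.70 (SD 0.05; range 0.58-0.78)
#>   frontal: n = 22, age 44.64 (SD 16.86)
#>   parietal: n = 5, age 55.60 (SD 19.06)
#>   temporal: n = 6, age 41.50 (SD 13.77)

lobe_composition(read_edge_table("temporal"), "increased")
#> Connections with increased end-point tract count: 21 unique regions
#>   central: 2/21 (10%)
#>   frontal: 3/21 (14%)
#>   limbic: 3/21 (14%)
#>   occipital: 7/21 (33%)
#>   parietal: 2/21 (10%)
#>   subcortical: 1/21 (5%)
#>   temporal: 3/21 (14%)
```

The first block recomputes the cohort's demographic summaries from the raw
table (mean age 45.73, 42%/58% sex split, pathology and grade fractions,
registration R² 0.70). The second collects the unique end-point regions of
the temporal group's 15 count-increased connections and tabulates them per
lobe — e.g. the occipital lobe contributes 7 of the 21 regions (33%).

A full synthetic run mirroring the study design:

```r
cfg <- pipeline_config(output_dir = "results/run", seed = 1)
res <- run_pipeline(cfg)
res$hemi                     # 12 hemispheric tests with FDR and direction
res$top_decile$frontal$nodes # 6 most-impacted regions for frontal lesions
res$screens$frontal          # per-connection CI screen with FA/MD follow-up
```

The same stages are available as narrative scripts under `analysis/`
(`01_simulate.R` … `05_edge_screen.R`), each writing its tables under
`results/`.

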