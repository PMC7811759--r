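---
title: "Hemispheric connectome analysis of lobe-localized glioma: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric connectome analysis of lobe-localized glioma: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiconn)
```

## The analysis

`hemiconn` implements a within-subject analysis of how a unilateral,
lobe-localized glioma reshapes the structural network of its hemisphere.
Each subject contributes six 56-node weighted undirected networks: one per
hemisphere (ipsilesional vs contralesional, the latter serving as the
within-subject control) for each of three DTI-derived edge weights —
end-point streamline count, fractional anisotropy (FA, dimensionless in
[0, 1]) and mean diffusivity (MD, on the 1e-3 mm²/s scale). Nodes are the 56
AAL2 regions of one hemisphere (vermis excluded); streamlines crossing the
midline are excluded upstream, so the two hemispheric networks are
disconnected by construction.

The pipeline has four statistical stages:

1. **Hemispheric distribution tests.** For each weighting and each of four
   nodal measures — weighted clustering coefficient (CC), local efficiency
   (LE), betweenness centrality (BC), eigenvector centrality (EC) — the
   ipsilesional and contralesional samples are log-transformed, screened for
   boxplot (Tukey) outliers, and compared with a two-sample Wilcoxon
   rank-sum test; the 12 p-values are Benjamini–Hochberg adjusted and called
   significant below 0.05.
2. **Highly impacted nodes.** Per node, the percent change
   `100 · (contralesional − ipsilesional) / ipsilesional` is computed for
   each weighting, averaged across the three weightings
   (`mean_percent_change`), and the nodes whose impact score falls in the
   top ten percentile (nearest-rank rule, exactly 6 of 56 under distinct
   values) form the group's `node_Top10` set.
3. **Lobar distribution tests.** The three groups' top-decile
   percent-change distributions are compared per measure with a
   Kruskal–Wallis H-test; pairwise Dunn z-tests (unadjusted) follow only
   when the H-test p-value is below 0.05.
4. **Connection screen.** Per lesion group and edge, the contralesional
   mean end-point count across subjects defines a two-sided 95% t-interval
   (`mean ± t(0.975, n−1)·SD/√n`); an ipsilesional mean outside the interval
   flags the connection as increased or decreased. FA and MD are then
   examined the same way, restricted to the count-flagged connections.

Stage 4 deserves a caveat it inherits from the original procedure: a group
*mean* is compared against a confidence interval for another mean, which is
a screening heuristic rather than a calibrated two-sample test — with many
subjects the interval shrinks and most edges become "significant". It is
implemented as printed, and no multiplicity correction is applied across
edges (a BH option exists for users who want one).

## Graph measures and numerical conventions

All four measures operate on a symmetric nonnegative weight matrix with zero
diagonal. Where a measure needs path lengths, weights convert as
`L = 1/w` (absent edge → infinite length), the Brain-Connectivity-Toolbox
convention for connection strengths.

- **CC** is the Onnela geometric-mean triangle intensity on weights scaled
  by the matrix maximum: `CC_i = Σ_(j,h) (ŵ_ij ŵ_ih ŵ_jh)^(1/3) / (k_i(k_i−1))`;
  degree < 2 gives 0.
- **LE** is the efficiency of the subgraph induced on a node's neighbours:
  the mean over neighbour pairs of `1/d`, with `d` the shortest-path length
  inside the induced subgraph on lengths `1/ŵ` (max-scaled weights, so
  `d ≥ 1` and LE ∈ [0, 1]); degree < 2 gives 0. The per-neighbourhood
  all-pairs distances run in compiled code (Floyd–Warshall).
- **BC** is Brandes betweenness on lengths `1/w`, with fractional credit for
  tied shortest paths, over unordered pairs, unnormalized by default (a
  `2/((n−1)(n−2))` flag exists); computed via igraph. Isolated nodes get NA.
- **EC** is the entrywise-nonnegative principal eigenvector of the weight
  matrix at unit Euclidean norm, by power iteration with a diagonal spectral
  shift (so bipartite ± eigenvalue pairs cannot stall convergence); an
  iteration budget overrun is an error, never a silent result.

MD is used directly as a connection weight, without inversion: the
reported MD-weighted effects (ipsilesional increases) are only coherent
under direct weighting, and no transform is stated in the source analyses.
All four measures are scale-invariant, which has a consequence worth
stating: a lesion effect that multiplies all count weights uniformly is
invisible to every stage-1 test, so whatever the count-weighted tests detect
is necessarily a *relative* reorganization — and any relative reweighting
also perturbs shortest paths, i.e. BC. The betweenness "null" result is
therefore a statement about effect size versus between-subject variability,
not about invariance.

Percent change is implemented exactly as the defining formula prints,
`(contra − ipsi)/ipsi × 100` — note the ipsilesional denominator, under
which an ipsilesional increase appears as a negative percent change. A
`direction` switch provides the conversational `(ipsi − contra)/contra`
convention; swapping roles maps `x` to `−100x/(100 + x)`, not to `−x`.
Group-level percent change averages the nodal measure over subjects per
(node, role, weighting) before taking the ratio; a per-subject mode is
available. The node impact score collapses the table to one value per node
as the mean over the four measures of |mean percent change|: "highly
impacted" is read as magnitude, since reported top-decile nodes carry both
signs.

Two pooling modes exist for stage 1 because the source is ambiguous. The
default, `subject_mean`, uses one hemispheric mean per subject per role
(2 × 33 sample points). The alternative, `pooled_nodes`, pools all nodal
values (33 × 56 per role). Pooled nodal values are pseudoreplicated — the
56 values of one hemisphere share subject- and hemisphere-level factors —
which makes the rank test anti-conservative; the subject-mean default is the
statistically defensible choice, and its null calibration is verified by
simulation (below). It is worth recording that reported EC p-values as small
as 1e-27 are not attainable from a rank-sum on 33 + 33 subject means (the
most extreme achievable two-sided p is about 3e-19), so analyses of that
scale must have pooled nodal values; users wanting to mirror that behaviour
can set `pooling = "pooled_nodes"`.

Other conventions: "log-normalized" is read as the natural log restricted to
strictly positive values (the measures are nonnegative with heavy right
tails; dropped values are counted and reported); outlier quartiles use
linear interpolation (R type 7); the normality screen pairs the
Anderson–Darling test with a Jarque–Bera skewness–kurtosis statistic and is
informational only — the pipeline is nonparametric regardless; the
Kruskal–Wallis gate uses the standard tie-corrected chi-square
approximation, and Dunn p-values are reported unadjusted because the source
procedure states a plain 0.05 threshold; the FDR family is the 12
(weighting × measure) tests of stage 1.

## The atlas table

The packaged lookup maps each of the 56 per-hemisphere AAL2 regions to one
of eight categories: frontal, parietal, temporal, occipital, limbic,
central, subcortical, cerebellum. Assignments for every region named in the
published connection analyses follow the categories used there (insula and
mid-cingulate limbic; fusiform grouped with occipital; Rolandic operculum
and postcentral gyrus central); the remaining regions carry conventional
AAL2 groupings and are flagged non-authoritative. One genuine ambiguity
exists: the postcentral gyrus is treated as parietal in one reported
composition and central in another; the canonical table uses central, which
reproduces every composition fraction the package asserts. Centroid
coordinates are plausible atlas-scale MNI values (left hemisphere tabulated,
right mirrored in x) used only for synthetic lesion placement and the
distance analysis; they are not measurement data.

## The synthetic cohort generator

No imaging data accompany the analysis, so the generator is the test bed
for every downstream stage. It emulates the study design — unilateral
lesions in 22 frontal, 5 parietal and 6 temporal subjects by default — and
the qualitative lesion signature: elevated ipsilesional end-point counts,
depressed FA, elevated MD, concentrated around the lesion lobe with
spatial decay.

**Baseline model.** A cohort-level population model assigns every node pair
a presence probability proportional to hub propensity times an exponential
distance rule (length scale 50 mm, scaled to an expected density of 0.45 on
56 nodes), plus population weights per kind. The modeled rich club is the
posterior-medial core (precuneus, posterior cingulate, superior/inferior
parietal, angular; hub factor 6), giving hub-hub "highway" edges with large
counts. FA rises and MD rises on core edges (`fa_hub_bonus`,
`md_hub_bonus`): major coherent bundles carry higher FA, and the
medial/periventricular core shows CSF-partial-volume-elevated MD. Besides
realism these offsets serve a numerical purpose: they anchor each matrix
maximum — the normalizer of CC and LE — on stable core edges, as in real
data, instead of letting it wander with noise.

**Subject and hemisphere structure.** Each subject draws its own topology
(Bernoulli presence per pair plus a random spanning tree, so every network
is connected) shared between its two hemispheres — the paired design needs
analogous edges. Subject-level weight noise perturbs the population values
with a size-dependent scale for counts: shares of major bundles are nearly
fixed while small tracts near the tracking threshold fluctuate
proportionally more. Each hemisphere then adds hemisphere-level noise, and
counts are realized as Poisson draws around the hemisphere intensity
(counting noise scales as √count), clamped at 1 to preserve topology; with
hemisphere noise disabled the realization is deterministic, so a null
lesion with all noise at zero yields exactly identical hemispheres.

**Lesion effect.** With distance `d` the mean of an edge's two end-point
distances to the lesion centroid (default: the mean centroid of the lesion
lobe's regions), ipsilesional counts are multiplied by
`1 + delta_count · exp(−d/decay_mm)` and FA/MD shifted additively by
`delta_fa · exp(−d/decay_mm)` and `delta_md · exp(−d/decay_mm)`. Defaults
`delta_count = 1.2`, `delta_fa = −0.08`, `delta_md = +0.20`,
`decay_mm = 70` were chosen so that the flagged-edge changes match the
magnitudes of the published group tables (FA drops of roughly 0.03–0.11, MD
rises of roughly 0.05–0.23, count increases of a few to ~20 streamlines)
with an effect that is strongest in the lesion lobe but extends across the
hemisphere, as infiltrative glioma effects do. FA/MD are clipped to valid
ranges after the shift; clipping more than 5% of edges raises a warning.

**What the generator does not emulate.** Mass-effect geometry, oedema as a
spatial process, new (spurious) ipsilesional connections — topology is
shared within subject, so density is identical between hemispheres — and
any coupling between tumour volume and effect size (volumes are simulated
independently, making the volume correlation a null check). Passing tests
against this generator therefore demonstrate that the statistical machinery
detects the modeled signature at realistic sizes and is calibrated under
its null; they do not validate the biological model itself.

## Operating characteristics and known limitations

Simulation suites (seeded, in `tests/testthat/test-acceptance.R`) verify at
the study's own dimensions (n = 33 subjects, 56 nodes):

- **Null calibration**: across 200 null-lesion cohorts the FDR-significant
  fraction of hemispheric tests stays within 3 percentage points of the
  nominal 0.05.
- **Direction pattern**: a count-inflating / FA-depressing / MD-elevating
  lesion reproduces the qualitative direction table (count CC/LE/EC up, FA
  CC/LE down, MD CC/LE/EC up, BC null) — see the caveat below.
- **Lesion recovery**: lesion-lobe regions are over-represented in the
  top-decile set relative to the hypergeometric null (aggregate test across
  100 cohorts of the frontal group size, n = 22), and count-flagged
  lesion-lobe edges are flagged FA-decreased / MD-increased in well over
  80% of cases, at table-scale magnitudes.

The direction-pattern suite exposes a genuine tension rather than a bug: at
n = 33 with two-sample tests on subject means, the count-weighted CC/LE
power and the BC null are coupled. Because the measures are scale-invariant,
a count inflation only moves CC/LE through *relative* reweighting, and the
same reweighting systematically reroutes shortest paths, draining hub
betweenness — a real, small, directional BC effect. Raising the inflation
powers CC/LE but makes the BC drain detectable; lowering it protects the BC
null but starves CC/LE. With effect sizes capped at the published tables'
magnitudes the joint pattern reproduces in roughly half the simulated
cohorts rather than the large majority, with the individual count-LE and
BC-null components each passing in about two-thirds to three-quarters. We
report this honestly instead of inflating effects beyond the published
scale: reproducing a BC null alongside strong CC/LE/EC effects evidently
requires between-subject variability structure (e.g. individual topologies
far more heterogeneous than weight noise) that printed group tables do not
constrain.

Other limitations: the region→lobe table outside the published analyses is
conventional rather than confirmed; the two tiny groups (parietal n = 5,
temporal n = 6) make their screens and lobar tests fragile, exactly as in
the original design; and the CI edge screen is a heuristic whose per-edge
flag rate under the null is governed by the exceedance probability of one
group mean against another mean's interval, not by a controlled error rate.

## Problem sizes used in the test suite

Simulation-based checks run at the study dimensions (56 nodes; cohorts of
33 or 22 subjects) with 100–200 replicate cohorts for calibration and
recovery suites and 100 random ≤6-node graphs for brute-force oracle
equivalence; the oracle tolerance is 1e-9 for CC/LE/BC and 1e-8 for EC
against dense eigendecomposition. `scripts/acceptance.R` recomputes the
same quantities at 30–40 replicates.
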