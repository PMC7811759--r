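Package: hemiconn
Title: Hemispheric Structural Connectome Analysis of Lobe-Localized Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of paired ipsilesional/contralesional hemispheric
    structural connectomes in patients with lobe-localized glioma. Computes
    weighted nodal graph measures (clustering coefficient, local efficiency,
    betweenness centrality, eigenvector centrality) on 56-node AAL2
    hemispheric networks weighted by end-point tract count, fractional
    anisotropy (FA) or mean diffusivity (MD); compares hemispheres with
    log-normalized, outlier-screened Wilcoxon tests under FDR control;
    identifies highly impacted nodes via a percent-change statistic with
    top-ten-percentile selection and lobar Kruskal-Wallis/Dunn testing; and
    screens individual connections with a contralesional 95% confidence
    interval on end-point tract count followed by FA/MD follow-up. Includes
    a seeded synthetic lesioned-connectome generator so the full pipeline is
    testable without imaging data, plus published group-level tables as
    worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    igraph,
    graphics,
    jsonlite,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
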