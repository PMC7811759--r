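# small named matrices for hand cases
named <- function(m) {
  dimnames(m) <- list(paste0("n", seq_len(nrow(m))), paste0("n", seq_len(nrow(m))))
  m
}
k3 <- named(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
path3 <- named(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))

test_that("weight-to-length follows the inverse convention", {
  w <- named(matrix(c(0, 2, 2, 0), 2))
  l <- weight_to_length(w)
  expect_equal(l[1, 2], 0.5)
  w0 <- named(matrix(0, 2, 2))
  expect_equal(weight_to_length(w0)[1, 2], Inf)
  expect_equal(weight_to_length(k3)[1, 2], 1)  # unit weights = hop counts
})

test_that("clustering coefficient matches hand-computed triangles", {
  expect_equal(unname(clustering_coefficient(k3)), rep(1, 3))
  expect_equal(unname(clustering_coefficient(path3)), rep(0, 3))
  tri_pend <- named(matrix(0, 4, 4))
  tri_pend[1, 2] <- tri_pend[1, 3] <- tri_pend[2, 3] <- tri_pend[3, 4] <- 1
  tri_pend <- tri_pend + t(tri_pend)
  expect_equal(unname(clustering_coefficient(tri_pend))[3], 1 / 3)
  expect_equal(unname(clustering_coefficient(tri_pend))[4], 0)
})

test_that("local efficiency matches definitions on degenerate cases", {
  iso <- named(matrix(0, 3, 3)); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(unname(local_efficiency(iso))[3], 0)   # isolated node
  expect_equal(unname(local_efficiency(iso))[1], 0)   # degree 1
  expect_equal(unname(local_efficiency(k3)), rep(1, 3))
})

test_that("betweenness matches hand counts", {
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))
  star <- named(matrix(0, 4, 4)); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(unname(betweenness_centrality(star)), c(3, 0, 0, 0))
  expect_equal(unname(betweenness_centrality(star, normalize = TRUE)),
               c(3 * 2 / (3 * 2), 0, 0, 0))
})

test_that("eigenvector centrality matches closed forms", {
  two <- named(matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(eigenvector_centrality(two)), rep(1 / sqrt(2), 2),
               tolerance = 1e-9)
  expect_equal(unname(eigenvector_centrality(k3)), rep(1 / sqrt(3), 3),
               tolerance = 1e-9)
  expect_equal(unname(eigenvector_centrality(path3)),
               c(0.5, sqrt(2) / 2, 0.5), tolerance = 1e-9)
})

test_that("measures match brute-force oracles on random small graphs", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:6, 1)
    w <- named(random_weighted_graph(n))
    expect_equal(unname(clustering_coefficient(w)), oracle_cc(w),
                 tolerance = 1e-9)
    expect_equal(unname(local_efficiency(w)), oracle_le(w), tolerance = 1e-9)
    expect_equal(unname(betweenness_centrality(w)), oracle_bc(w),
                 tolerance = 1e-9)
    ev <- eigen(w, symmetric = TRUE)$vectors[, 1]
    ev <- abs(ev) / sqrt(sum(ev^2))
    expect_equal(unname(eigenvector_centrality(w)), ev, tolerance = 1e-8)
  }
})

test_that("measures are permutation- and scale-invariant", {
  set.seed(9)
  w <- named(random_weighted_graph(6))
  perm <- sample(6)
  wp <- w[perm, perm]
  for (f in list(clustering_coefficient, local_efficiency,
                 betweenness_centrality, eigenvector_centrality)) {
    expect_equal(f(wp)[rownames(w)], f(w)[rownames(w)], tolerance = 1e-9)
  }
  for (f in list(clustering_coefficient, local_efficiency,
                 betweenness_centrality, eigenvector_centrality)) {
    expect_equal(f(w * 7.3), f(w), tolerance = 1e-9)
  }
})

test_that("equal weights reduce to the binary measures", {
  set.seed(11)
  w <- named(random_weighted_graph(6))
  b <- (w > 0) * 1
  expect_equal(clustering_coefficient(b * 2.5), clustering_coefficient(b),
               tolerance = 1e-12)
  g <- igraph::graph_from_adjacency_matrix(b, mode = "undirected")
  expect_equal(unname(betweenness_centrality(b)),
               unname(igraph::betweenness(g)), tolerance = 1e-9)
})

test_that("cohort metric table has full coverage and is deterministic", {
  coh <- tiny_cohort(n = 2, seed = 3)
  m <- compute_nodal_metrics(coh)
  expect_equal(nrow(m), 2 * 2 * 3 * 56)
  expect_false(anyNA(m$cc))
  m2 <- compute_nodal_metrics(coh)
  expect_identical(m, m2)
  broken <- coh
  broken$connectomes$S01$ipsilesional$FA <- NULL
  expect_error(compute_nodal_metrics(broken), "S01.*FA|FA.*S01")
})

test_that("a noise-free null lesion gives identical hemispheric metrics", {
  cfg <- generator_config(n_subjects = 1, seed = 5,
                          noise_subject_count = 0, noise_hemi_count = 0,
                          noise_subject_fa = 0, noise_hemi_fa = 0,
                          noise_subject_md = 0, noise_hemi_md = 0)
  coh <- generate_cohort(cfg, lesion_model("frontal", delta_count = 0,
                                           delta_fa = 0, delta_md = 0))
  m <- compute_nodal_metrics(coh)
  ipsi <- m[m$role == "ipsilesional", c("cc", "le", "bc", "ec")]
  contra <- m[m$role == "contralesional", c("cc", "le", "bc", "ec")]
  expect_equal(unname(as.matrix(ipsi)), unname(as.matrix(contra)))
})
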