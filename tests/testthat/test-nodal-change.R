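test_that("percent change follows the printed formula with NA guards", {
  expect_equal(percent_change(120, 100), 20)
  expect_equal(percent_change(5, 5), 0)
  expect_true(is.na(percent_change(7, 0)))
  expect_true(is.na(percent_change(NA, 3)))
  expect_equal(percent_change(100, 120, direction = "ipsi_vs_contra"), 20)
  # swapping roles maps x to -100 x / (100 + x)
  x <- percent_change(130, 80)
  swapped <- percent_change(80, 130)
  expect_equal(swapped, -100 * x / (100 + x))
})

test_that("mean percent change averages the three weights with NA propagation", {
  expect_equal(mean_percent_change(10, -20, 40), 10)
  expect_equal(mean_percent_change(0, 0, 0), 0)
  expect_true(is.na(mean_percent_change(NA, 5, 5)))
})

test_that("group-level percent-change table averages subjects before the ratio", {
  m <- rbind(
    data.frame(case_id = c("A", "B"), role = "ipsilesional",
               weight_kind = "count", node = "X", cc = c(2, 4), le = 1,
               bc = 1, ec = 1),
    data.frame(case_id = c("A", "B"), role = "contralesional",
               weight_kind = "count", node = "X", cc = c(4, 8), le = 1,
               bc = 1, ec = 1),
    data.frame(case_id = c("A", "B"), role = rep(c("ipsilesional",
                                                   "contralesional"),
                                                 each = 2),
               weight_kind = rep(c("FA", "MD"), 2), node = "X",
               cc = 1, le = 1, bc = 1, ec = 1)
  )
  tab <- percent_change_table(m)
  cc_row <- tab[tab$metric == "cc", ]
  expect_equal(cc_row$pct_count, 100 * (6 - 3) / 3)  # group means 6 vs 3
  expect_equal(cc_row$pct_fa, 0)
  expect_equal(cc_row$mean_pct, (100 + 0 + 0) / 3)
})

test_that("top-decile selection uses the nearest-rank rule", {
  v <- stats::setNames(seq_len(56) + 0.1, paste0("r", 1:56))
  td <- top_decile_nodes(v)
  expect_length(td$nodes, 6)
  expect_setequal(td$nodes, paste0("r", 51:56))
  expect_equal(td$threshold, v[["r51"]])
  # NAs rank last
  v2 <- v; v2[c("r55", "r56")] <- NA
  td2 <- top_decile_nodes(v2)
  expect_setequal(td2$nodes, paste0("r", 49:54))
  expect_warning(td3 <- top_decile_nodes(stats::setNames(rep(1, 56),
                                                         names(v))),
                 "tie")
  expect_length(td3$nodes, 56)
  expect_error(top_decile_nodes(stats::setNames(rep(NA_real_, 5),
                                                paste0("r", 1:5))),
               "all node scores")
})

test_that("Kruskal-Wallis gate and Dunn z match hand computation", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(11, 12, 13))
  lt <- lobar_distribution_test(groups)
  expect_equal(lt$h, 7.2, tolerance = 1e-9)   # 12/90 * 3*(4+25+64) - 30
  expect_lt(lt$p_value, 0.05)
  expect_false(is.null(lt$dunn))
  ac <- lt$dunn[lt$dunn$group_a == "a" & lt$dunn$group_b == "c", ]
  # z = (2 - 8) / sqrt(7.5 * (1/3 + 1/3)), no ties
  expect_equal(ac$z, -6 / sqrt(7.5 * 2 / 3), tolerance = 1e-9)
  expect_equal(ac$p_value, 2 * pnorm(-6 / sqrt(5)), tolerance = 1e-9)
  ab <- lt$dunn[lt$dunn$group_a == "a" & lt$dunn$group_b == "b", ]
  expect_gt(ab$p_value, 0.05)
})

test_that("Dunn stage is skipped for indistinguishable groups", {
  same <- list(a = c(1, 2, 3), b = c(1.1, 2.1, 3.1), c = c(0.9, 1.9, 2.9))
  lt <- lobar_distribution_test(same)
  expect_gt(lt$p_value, 0.05)
  expect_null(lt$dunn)
  expect_error(lobar_distribution_test(list(a = 1, b = c(1, 2), c = c(1, 2))),
               "at least 2")
})

test_that("relabelling groups permutes Dunn rows consistently", {
  set.seed(4)
  v <- list(a = rnorm(6), b = rnorm(6, 2), c = rnorm(6, 4))
  d1 <- dunn_test(unlist(v), rep(names(v), each = 6))
  relab <- c(a = "c", b = "a", c = "b")
  d2 <- dunn_test(unlist(v), relab[rep(names(v), each = 6)])
  z1 <- d1$z[d1$group_a == "a" & d1$group_b == "b"]
  z2 <- d2$z[d2$group_a == "a" & d2$group_b == "c"]   # (b,a) under new labels
  expect_equal(abs(z2), abs(z1), tolerance = 1e-12)
})

test_that("volume correlation matches the closed-form Pearson formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 3.9, 6.2, 8.1, 9.9)
  r <- correlate_volume(x, y)
  rr <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r, rr, tolerance = 1e-12)
  tt <- rr * sqrt(3 / (1 - rr^2))
  expect_equal(r$p_value, 2 * pt(-abs(tt), df = 3), tolerance = 1e-12)
  expect_equal(correlate_volume(1:4, 2 * (1:4))$r, 1)
  expect_warning(rz <- correlate_volume(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(rz$r))
})

test_that("volume-independent effects give null volume correlations", {
  hits <- 0; n_seeds <- 20
  set.seed(77)
  for (s in 1:n_seeds) {
    pct <- rnorm(33, 10, 15)           # per-subject mean %change
    vol <- rlnorm(33, 3, 0.6)          # volumes drawn independently
    r <- correlate_volume(pct, vol)
    hits <- hits + (r$p_value > 0.05)
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("distance correlation recovers the spatial decay of the lesion", {
  det_neg <- 0; null_ns <- 0; n_seeds <- 8
  for (s in 1:n_seeds) {
    cfg <- generator_config(n_subjects = 10, seed = 500 + s)
    coh <- generate_cohort(cfg, lesion_model("frontal"))
    pct <- percent_change_table(compute_nodal_metrics(coh))
    les <- coh$ground_truth$lesions[[1]]
    dc <- correlate_distance(pct, les$centroid)
    fa_cc <- dc[dc$metric == "cc" & dc$weight_kind == "FA", ]
    det_neg <- det_neg + (fa_cc$r < 0 && fa_cc$p_value < 0.05)
    cfg2 <- generator_config(n_subjects = 10, seed = 600 + s)
    coh2 <- generate_cohort(cfg2, lesion_model("frontal", delta_count = 0,
                                               delta_fa = 0, delta_md = 0))
    pct2 <- percent_change_table(compute_nodal_metrics(coh2))
    dc2 <- correlate_distance(pct2, les$centroid)
    fa_cc2 <- dc2[dc2$metric == "cc" & dc2$weight_kind == "FA", ]
    null_ns <- null_ns + (fa_cc2$p_value > 0.05)
  }
  expect_gte(det_neg / n_seeds, 0.75)
  expect_gte(null_ns / n_seeds, 0.75)
  cen0 <- node_centroids("L"); cen0[, ] <- 1
  w <- testthat::capture_warnings(
    dc0 <- correlate_distance(
      percent_change_table(compute_nodal_metrics(tiny_cohort(n = 3))),
      c(0, 0, 0), centroids = cen0))
  expect_true(any(grepl("degenerate", w)))
  expect_true(all(is.na(dc0$r)))
})
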