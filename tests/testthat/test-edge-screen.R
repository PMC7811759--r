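# build a 3-subject cohort whose matrices are zero except chosen edges
handmade_cohort <- function(contra_vals, ipsi_vals, edge = c("SFG", "MFG"),
                            extra = list()) {
  labels <- atlas_labels()
  n_sub <- length(contra_vals)
  blank <- matrix(0, 56, 56, dimnames = list(labels, labels))
  cons <- list()
  for (i in seq_len(n_sub)) {
    ci <- blank; ci[edge[1], edge[2]] <- ci[edge[2], edge[1]] <- contra_vals[i]
    ii <- blank; ii[edge[1], edge[2]] <- ii[edge[2], edge[1]] <- ipsi_vals[i]
    for (e in extra) {
      ci[e$edge[1], e$edge[2]] <- ci[e$edge[2], e$edge[1]] <- e$contra[i]
      ii[e$edge[1], e$edge[2]] <- ii[e$edge[2], e$edge[1]] <- e$ipsi[i]
    }
    cons[[sprintf("H%d", i)]] <- list(
      ipsilesional = list(count = ii, FA = ii / 100, MD = ii / 50),
      contralesional = list(count = ci, FA = ci / 100, MD = ci / 50))
  }
  structure(list(subjects = data.frame(case_id = names(cons),
                                       lobe = "frontal"),
                 connectomes = cons, labels = labels),
            class = "glioma_cohort")
}

test_that("zero-variance contralesional edges give point intervals", {
  coh <- handmade_cohort(c(10, 10, 10), c(12, 12, 12))
  scr <- edge_ci_screen(coh)
  row <- scr[scr$node_a == "MFG" | scr$node_b == "MFG", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$significance, "increased")
  expect_equal(row$mean_change, 2)
  expect_equal(row$ci_lower, row$ci_upper)
})

test_that("the t interval matches the hand computation (t_{0.975,2} = 4.303)", {
  coh_ns <- handmade_cohort(c(8, 10, 12), c(14, 14, 14))
  row <- edge_ci_screen(coh_ns)
  expect_equal(row$contra_mean, 10)
  expect_equal(row$ci_upper, 10 + qt(0.975, 2) * 2 / sqrt(3), tolerance = 1e-9)
  expect_equal(row$significance, "ns")
  expect_true(is.na(row$mean_change))
  coh_sig <- handmade_cohort(c(8, 10, 12), c(20, 20, 20))
  expect_equal(edge_ci_screen(coh_sig)$significance, "increased")
  coh_dec <- handmade_cohort(c(8, 10, 12), c(2, 2, 2))
  expect_equal(edge_ci_screen(coh_dec)$significance, "decreased")
})

test_that("widening the interval never adds significant edges", {
  coh <- tiny_cohort(n = 6, seed = 91)
  s95 <- edge_ci_screen(coh, level = 0.95)
  s99 <- edge_ci_screen(coh, level = 0.99)
  key <- paste(s95$node_a, s95$node_b)
  sig95 <- key[s95$significance != "ns"]
  sig99 <- paste(s99$node_a, s99$node_b)[s99$significance != "ns"]
  expect_true(all(sig99 %in% sig95))
})

test_that("FA/MD follow-up is restricted to count-significant edges", {
  coh <- handmade_cohort(c(8, 10, 12), c(14, 14, 14),
                         extra = list(list(edge = c("STG", "MTG"),
                                           contra = c(10, 10, 10),
                                           ipsi = c(30, 30, 30))))
  scr <- diffusion_followup(edge_ci_screen(coh), coh)
  ns_row <- scr[scr$node_a == "MFG" | scr$node_b == "MFG", ]
  expect_true(is.na(ns_row$fa_contra) && is.na(ns_row$fa_sig))
  sig_row <- scr[scr$node_a == "STG", ]
  expect_equal(sig_row$significance, "increased")
  # FA/MD here are count/100 and count/50, so both follow the count upward
  expect_equal(sig_row$fa_sig, "increased")
  expect_equal(sig_row$md_sig, "increased")
  expect_equal(sig_row$fa_contra, 0.1)
})

test_that("errors surface for small groups and missing matrices", {
  coh <- tiny_cohort(n = 2, seed = 92)
  expect_error(edge_ci_screen(coh), "at least 3")
  coh3 <- tiny_cohort(n = 3, seed = 93)
  scr <- edge_ci_screen(coh3)
  broken <- coh3
  for (cid in names(broken$connectomes)) {
    broken$connectomes[[cid]]$ipsilesional$FA <- NULL
  }
  expect_error(diffusion_followup(scr, broken), "missing matrix")
})

test_that("lobe composition counts unique regions with rounded percentages", {
  fr <- lobe_composition(read_edge_table("frontal"), "increased")
  expect_equal(fr$denominator, 8)
  tab <- stats::setNames(fr$table$pct, fr$table$lobe)
  expect_equal(unname(tab["temporal"]), 25)
  expect_equal(unname(tab["cerebellum"]), 25)
  expect_equal(unname(tab["limbic"]), 13)
  expect_equal(sum(fr$table$count), 8)
  # denominator always equals the union of end points
  scr <- edge_ci_screen(tiny_cohort(n = 5, seed = 94))
  comp <- lobe_composition(scr, "increased")
  sig <- scr[scr$significance == "increased", ]
  expect_equal(comp$denominator, length(unique(c(sig$node_a, sig$node_b))))
  expect_equal(sum(comp$table$count), comp$denominator)
  empty <- lobe_composition(read_edge_table("temporal"), "decreased")
  expect_equal(empty$denominator, 0)
  expect_equal(nrow(empty$table), 0)
})
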