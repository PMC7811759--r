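#' Pipeline configuration
#'
#' Collects every tunable of the full analysis in one object. Defaults
#' mirror the study design: 33 subjects split 22 frontal / 5 parietal / 6
#' temporal, subject-mean pooling, the printed percent-change convention,
#' 95% edge CI, nearest-rank top decile, FDR alpha 0.05.
#'
#' @param output_dir Where stage outputs are written.
#' @param cohort_dir Optional directory of an existing cohort (written by
#'   [write_cohort()]); when NULL a synthetic cohort is generated.
#' @param group_sizes Named vector of subjects per lesion lobe for the
#'   simulate stage.
#' @param lesion Default `lesion_model` parameters (list passed to
#'   [lesion_model()] minus `lobe`).
#' @param pooling,pct_direction,ci_level,alpha See the stage functions.
#' @param seed Master seed.
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "metrics", "hemi_test", "nodal_change", "edge_screen")`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            cohort_dir = NULL,
                            group_sizes = c(frontal = 22L, parietal = 5L,
                                            temporal = 6L),
                            lesion = list(),
                            pooling = "subject_mean",
                            pct_direction = "contra_vs_ipsi",
                            ci_level = 0.95, alpha = 0.05, seed = 1L,
                            stages = c("simulate", "metrics", "hemi_test",
                                       "nodal_change", "edge_screen")) {
  stopifnot(alpha > 0, alpha < 1, ci_level > 0, ci_level < 1)
  structure(list(output_dir = output_dir, cohort_dir = cohort_dir,
                 group_sizes = group_sizes, lesion = lesion,
                 pooling = pooling, pct_direction = pct_direction,
                 ci_level = ci_level, alpha = alpha, seed = as.integer(seed),
                 stages = stages),
            class = "pipeline_config")
}

#' Run the full hemispheric-connectome pipeline
#'
#' Executes simulate (or load) -> nodal metrics -> hemispheric tests ->
#' percent change / top decile / lobar tests -> per-group edge screen, and
#' writes each stage's table under `config$output_dir`. Reproducible given
#' the seed.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with every stage result (`cohort`, `metrics`,
#'   `hemi`, `pct`, `top_decile`, `lobar`, `screens`, `compositions`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    message("stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  res$cohort <- stage("simulate", {
    if (!is.null(config$cohort_dir)) {
      read_cohort(config$cohort_dir)
    } else {
      lobes <- rep(names(config$group_sizes), config$group_sizes)
      lesions <- lapply(lobes, function(lb) {
        do.call(lesion_model, c(list(lobe = lb), config$lesion))
      })
      cfg <- generator_config(n_subjects = length(lobes), seed = config$seed)
      cohort <- generate_cohort(cfg, lesions)
      utils::write.csv(cohort$subjects,
                       file.path(config$output_dir, "subjects.csv"),
                       row.names = FALSE)
      cohort
    }
  })
  if (!"metrics" %in% config$stages) return(invisible(res))

  res$metrics <- stage("metrics", compute_nodal_metrics(res$cohort))
  utils::write.csv(res$metrics, file.path(config$output_dir, "nodal_metrics.csv"),
                   row.names = FALSE)
  if (!"hemi_test" %in% config$stages) return(invisible(res))

  res$hemi <- stage("hemi_test",
                    hemispheric_test(res$metrics, pooling = config$pooling,
                                     alpha = config$alpha))
  utils::write.csv(res$hemi, file.path(config$output_dir, "hemispheric_tests.csv"),
                   row.names = FALSE)
  if (!"nodal_change" %in% config$stages) return(invisible(res))

  stage("nodal_change", {
    subjects <- res$cohort$subjects
    res$pct <- list()
    res$top_decile <- list()
    for (lb in unique(subjects$lobe)) {
      ids <- subjects$case_id[subjects$lobe == lb]
      tab <- percent_change_table(res$metrics[res$metrics$case_id %in% ids, ],
                                  level = "group",
                                  direction = config$pct_direction)
      res$pct[[lb]] <- tab
      res$top_decile[[lb]] <- top_decile_nodes(node_impact_scores(tab),
                                                group = lb)
      utils::write.csv(tab, file.path(config$output_dir,
                                      sprintf("percent_change_%s.csv", lb)),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(res$top_decile, function(s) list(group = s$group,
                                              threshold = s$threshold,
                                              nodes = s$nodes)),
      file.path(config$output_dir, "top_decile_sets.json"),
      auto_unbox = TRUE, digits = NA)
    # lobar tests: per measure, the three top-decile sets' mean %change
    # evaluated within each lesion group
    lobar <- list()
    for (lb in names(res$pct)) {
      for (ms in c("cc", "le", "bc", "ec")) {
        tab <- res$pct[[lb]]
        sets <- lapply(res$top_decile, function(s) {
          v <- tab$mean_pct[tab$metric == ms & tab$node %in% s$nodes]
          v[is.finite(v)]
        })
        if (any(vapply(sets, length, 1L) < 2)) next
        lt <- lobar_distribution_test(sets, alpha = config$alpha)
        lobar[[paste(lb, ms)]] <- data.frame(lesion_group = lb, metric = ms,
                                             h = lt$h, p_value = lt$p_value)
      }
    }
    res$lobar <- do.call(rbind, lobar)
    utils::write.csv(res$lobar, file.path(config$output_dir, "lobar_tests.csv"),
                     row.names = FALSE)
  })
  if (!"edge_screen" %in% config$stages) return(invisible(res))

  stage("edge_screen", {
    res$screens <- list()
    res$compositions <- list()
    subjects <- res$cohort$subjects
    for (lb in unique(subjects$lobe)) {
      ids <- subjects$case_id[subjects$lobe == lb]
      if (length(ids) < 3) next
      sub <- list(subjects = subjects[subjects$lobe == lb, ],
                  connectomes = res$cohort$connectomes[ids],
                  labels = res$cohort$labels)
      class(sub) <- "glioma_cohort"
      scr <- edge_ci_screen(sub, level = config$ci_level)
      scr <- diffusion_followup(scr, sub, level = config$ci_level)
      res$screens[[lb]] <- scr
      res$compositions[[lb]] <- list(
        increased = lobe_composition(scr, "increased"),
        decreased = lobe_composition(scr, "decreased"))
      utils::write.csv(scr[scr$significance != "ns", ],
                       file.path(config$output_dir,
                                 sprintf("edge_screen_%s.csv", lb)),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(res$compositions, function(cc) lapply(cc, function(x) {
        list(direction = x$direction, denominator = x$denominator,
             regions = x$regions, table = x$table)
      })),
      file.path(config$output_dir, "lobe_compositions.json"),
      auto_unbox = TRUE, digits = NA)
  })
  invisible(res)
}
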