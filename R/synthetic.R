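#' Lesion model for the synthetic generator
#'
#' Describes the edge-weight footprint of a lobe-localized glioma: a
#' multiplicative inflation of end-point tract count, an additive depression
#' of FA and an additive elevation of MD, each attenuated with Euclidean
#' distance from the lesion centroid as exp(-d / decay_mm), where d is the
#' mean of the two end-point centroid distances. The defaults mirror the
#' effect magnitudes reported for real lesion groups (FA drops of about
#' 0.03-0.11 and MD rises of about 0.05-0.23 on affected connections) and a
#' count inflation of the order of tens of streamlines on typical edges.
#'
#' @param lobe Lesion lobe category ("frontal", "parietal", "temporal" or
#'   "occipital").
#' @param delta_count Multiplicative count inflation at the lesion core
#'   (>= 0; 0.6 means +60%).
#' @param delta_fa Additive FA change at the core (<= 0).
#' @param delta_md Additive MD change at the core (>= 0, 1e-3 mm^2/s scale).
#' @param decay_mm Spatial decay length (> 0; `Inf` gives a uniform
#'   hemispheric effect).
#' @param centroid Optional 3-vector (mm); defaults to the mean centroid of
#'   the lesion lobe's regions.
#' @return List of class `lesion_model`.
#' @export
lesion_model <- function(lobe = "frontal", delta_count = 1.2,
                         delta_fa = -0.08, delta_md = 0.20,
                         decay_mm = 70, centroid = NULL) {
  lobe <- match.arg(lobe, c("frontal", "parietal", "temporal", "occipital"))
  stopifnot(delta_count >= 0, delta_fa <= 0, delta_md >= 0, decay_mm > 0)
  if (is.null(centroid)) {
    cen <- node_centroids("L")
    centroid <- colMeans(cen[lobe_of(rownames(cen)) == lobe, , drop = FALSE])
  }
  stopifnot(length(centroid) == 3)
  structure(list(lobe = lobe, delta_count = delta_count, delta_fa = delta_fa,
                 delta_md = delta_md, decay_mm = decay_mm,
                 centroid = as.numeric(centroid)),
            class = "lesion_model")
}

#' Generator configuration
#'
#' Baseline model for paired hemispheric connectomes. A cohort-level
#' population model is drawn first: every node pair gets a presence
#' probability (hub propensity times an exponential distance rule, scaled to
#' the target density) and population weights for the three kinds, giving
#' the core-periphery organization of real structural connectomes with a
#' posterior-medial rich club. Each subject then draws its own topology
#' (Bernoulli presence plus a random spanning tree for connectivity) shared
#' between the two hemispheres, perturbs the population weights at the
#' subject level, and realizes each hemisphere with hemisphere-level noise;
#' counts are Poisson draws around the hemisphere intensity (counting noise
#' scales as sqrt(count)), clamped at 1 to preserve the shared topology. FA
#' is truncated to \[0.01, 0.99\]; MD is kept positive.
#'
#' @param n_subjects Number of subjects.
#' @param edge_density Fraction of the 1540 node pairs connected (0, 1].
#' @param count_meanlog,count_sdlog Location/scale of the population
#'   log-normal for count weights (before the hub bonus).
#' @param fa_mean,fa_sd Population FA mean and between-edge SD.
#' @param md_mean,md_sd Population MD mean and between-edge SD
#'   (1e-3 mm^2/s scale).
#' @param noise_subject_count,noise_hemi_count Log-scale SD of the
#'   subject-level and hemisphere-level multiplicative noise on count
#'   intensities at the reference count `exp(count_meanlog)`; the applied SD
#'   shrinks with bundle size (shares of major bundles are stable, small
#'   tracts near the tracking threshold fluctuate proportionally more).
#' @param noise_subject_fa,noise_hemi_fa Additive FA noise SDs.
#' @param noise_subject_md,noise_hemi_md Additive MD noise SDs.
#' @param hub_labels Regions given elevated connection propensity and
#'   stronger count weights (defaults to the posterior-medial structural
#'   core reported for human connectomes: precuneus, posterior cingulate,
#'   superior/inferior parietal, angular gyrus, thalamus).
#' @param hub_factor Propensity multiplier for hub regions.
#' @param fa_hub_bonus,md_hub_bonus Additive FA/MD offsets at maximal edge
#'   coreness (hub-hub edges): major coherent bundles carry higher FA, and
#'   the medial/periventricular core shows CSF-partial-volume-elevated MD.
#'   These anchor each matrix maximum on stable core edges, as in real data.
#' @param edr_mm Exponential-distance-rule length scale for edge presence:
#'   short-range connections are near-universal across subjects, long-range
#'   ones sparse and variable.
#' @param presence_jitter Log-scale SD of cohort-level heterogeneity in the
#'   per-pair presence probability.
#' @param centroids 56 x 3 centroid matrix (defaults to the packaged atlas).
#' @param seed Integer master seed; identical configuration and seed give a
#'   byte-identical cohort.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 33L, edge_density = 0.45,
                             count_meanlog = 3.0, count_sdlog = 0.35,
                             fa_mean = 0.35, fa_sd = 0.04,
                             md_mean = 0.90, md_sd = 0.08,
                             noise_subject_count = 0.30,
                             noise_hemi_count = 0.35,
                             noise_subject_fa = 0.015, noise_hemi_fa = 0.010,
                             noise_subject_md = 0.020, noise_hemi_md = 0.015,
                             hub_labels = c("PCUN", "PCC", "SPG", "IPG",
                                            "ANG"),
                             hub_factor = 6,
                             fa_hub_bonus = 0.12, md_hub_bonus = 0.30,
                             edr_mm = 50, presence_jitter = 1.0,
                             centroids = NULL, seed = 1L) {
  stopifnot(n_subjects >= 1, edge_density > 0, edge_density <= 1,
            hub_factor >= 1)
  if (is.null(centroids)) centroids <- node_centroids("L")
  stopifnot(nrow(centroids) == 56, ncol(centroids) == 3)
  structure(list(n_subjects = as.integer(n_subjects),
                 edge_density = edge_density,
                 count_meanlog = count_meanlog, count_sdlog = count_sdlog,
                 fa_mean = fa_mean, fa_sd = fa_sd,
                 md_mean = md_mean, md_sd = md_sd,
                 noise_subject_count = noise_subject_count,
                 noise_hemi_count = noise_hemi_count,
                 noise_subject_fa = noise_subject_fa,
                 noise_hemi_fa = noise_hemi_fa,
                 noise_subject_md = noise_subject_md,
                 noise_hemi_md = noise_hemi_md,
                 hub_labels = hub_labels, hub_factor = hub_factor,
                 fa_hub_bonus = fa_hub_bonus, md_hub_bonus = md_hub_bonus,
                 edr_mm = edr_mm, presence_jitter = presence_jitter,
                 centroids = centroids, seed = as.integer(seed)),
            class = "generator_config")
}

# cohort-level population model over all node pairs: presence probability
# (hub propensity x exponential distance rule, scaled to the target density)
# and population weights for the three kinds; subjects draw their own
# topology from the presence probabilities
draw_population <- function(config) {
  labels <- rownames(config$centroids)
  n <- length(labels)
  prop <- ifelse(labels %in% config$hub_labels, config$hub_factor, 1)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  m <- nrow(pairs)
  dxy <- config$centroids[pairs[, 1], ] - config$centroids[pairs[, 2], ]
  d_edge <- sqrt(rowSums(dxy^2))
  hubw <- prop[pairs[, 1]] * prop[pairs[, 2]]
  coreness <- (sqrt(hubw) - 1) / (config$hub_factor - 1)
  pi_raw <- hubw * exp(-d_edge / config$edr_mm +
                         stats::rnorm(m, 0, config$presence_jitter))
  m_target <- config$edge_density * m
  pi <- pmin(0.98, pi_raw * m_target / sum(pi_raw))
  list(
    labels = labels, pairs = pairs, prop = prop, presence = pi,
    count = exp(config$count_meanlog + log(hubw) +
                  stats::rnorm(m, 0, config$count_sdlog)),
    fa = pmin(0.99, pmax(0.01, config$fa_hub_bonus * coreness +
                           stats::rnorm(m, config$fa_mean, config$fa_sd))),
    md = pmax(0.05, config$md_hub_bonus * coreness +
                stats::rnorm(m, config$md_mean, config$md_sd)),
    # mean end-point distance of each edge to a point, for the lesion decay
    mid_d = function(centroid) {
      d <- sqrt(rowSums(sweep(config$centroids, 2, centroid)^2))
      (d[pairs[, 1]] + d[pairs[, 2]]) / 2
    }
  )
}

# subject topology: Bernoulli presence per pair plus a random spanning tree
# so every hemisphere network is connected
draw_topology <- function(population) {
  n <- length(population$labels)
  present <- stats::runif(nrow(population$pairs)) < population$presence
  ord <- sample.int(n)
  prop <- population$prop
  key <- population$pairs[, 1] * (n + 1L) + population$pairs[, 2]
  for (i in 2:n) {
    j <- ord[sample.int(i - 1L, 1L, prob = prop[ord[1:(i - 1)]])]
    a <- min(j, ord[i]); b <- max(j, ord[i])
    present[match(a * (n + 1L) + b, key)] <- TRUE
  }
  present
}

edges_to_matrix <- function(labels, edges, values) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[edges] <- values
  m[edges[, c(2, 1), drop = FALSE]] <- values
  m
}

#' Generate one subject's six connectomes
#'
#' Draws the subject's weight template around the supplied population
#' network, realizes the two hemispheres with independent hemisphere-level
#' noise, and applies the lesion effect to the ipsilesional hemisphere:
#' counts are multiplied by (1 + delta_count * exp(-d / decay_mm)) and FA/MD
#' receive the analogous additive change. Both hemispheres share the binary
#' topology, so percent change is defined edge-wise.
#'
#' @param config A `generator_config`.
#' @param lesion A `lesion_model`.
#' @param subject_seed Integer seed for this subject.
#' @param case_id Subject identifier.
#' @param population Optional population draw (internal; built from
#'   `config$seed` when absent).
#' @return List with `record` (one-row subject data.frame), `matrices`
#'   (`$ipsilesional` / `$contralesional`, each with `$count`, `$FA`, `$MD`)
#'   and `clipped_fraction` (fraction of lesioned edges clipped at the
#'   FA/MD bounds; a warning is raised above 5%).
#' @export
generate_subject <- function(config, lesion, subject_seed,
                             case_id = "S1", population = NULL) {
  stopifnot(inherits(config, "generator_config"),
            inherits(lesion, "lesion_model"))
  if (is.null(population)) {
    set.seed(config$seed)
    population <- draw_population(config)
  }
  set.seed(subject_seed)
  pop <- population
  present <- draw_topology(pop)
  ei <- pop$pairs[present, , drop = FALSE]
  m <- nrow(ei)
  f_lesion <- exp(-pop$mid_d(lesion$centroid)[present] / lesion$decay_mm)
  # between-subject variability of a connection's count share shrinks with
  # bundle size: major bundles have near-fixed shares, small tracts near the
  # tracking threshold fluctuate proportionally more
  size_scale <- pmin(4, (exp(config$count_meanlog) / pop$count[present]))^0.75
  subj_count <- pop$count[present] *
    exp(stats::rnorm(m, 0, config$noise_subject_count * size_scale))
  subj_fa <- pop$fa[present] + stats::rnorm(m, 0, config$noise_subject_fa)
  subj_md <- pop$md[present] + stats::rnorm(m, 0, config$noise_subject_md)
  hemi <- function(lesioned) {
    lam <- subj_count *
      exp(stats::rnorm(m, 0, config$noise_hemi_count * size_scale))
    fa <- subj_fa + stats::rnorm(m, 0, config$noise_hemi_fa)
    md <- subj_md + stats::rnorm(m, 0, config$noise_hemi_md)
    clipped <- 0
    if (lesioned) {
      lam <- lam * (1 + lesion$delta_count * f_lesion)
      fa <- fa + lesion$delta_fa * f_lesion
      md <- md + lesion$delta_md * f_lesion
      clipped <- mean(fa < 0.01 | fa > 0.99 | md < 0.05)
    }
    # counts are realized as Poisson draws around the subject intensity:
    # streamline counting noise scales as sqrt(count), so large bundles have
    # stable shares while small connections fluctuate; clamped at 1 to
    # preserve the within-subject shared topology. With hemisphere noise
    # disabled the realization is deterministic (rounded intensity), so a
    # null lesion with zero noise gives identical hemispheres.
    list(count = if (config$noise_hemi_count > 0) {
           pmax(1, stats::rpois(m, lam))
         } else {
           pmax(1, round(lam))
         },
         FA = pmin(0.99, pmax(0.01, fa)),
         MD = pmax(0.05, md),
         clipped = clipped)
  }
  contra <- hemi(FALSE)
  ipsi <- hemi(TRUE)
  if (ipsi$clipped > 0.05) {
    warning(sprintf("lesion effect clipped %.1f%% of edges at the FA/MD bounds",
                    100 * ipsi$clipped))
  }
  mats <- list(
    ipsilesional = lapply(ipsi[c("count", "FA", "MD")],
                          function(v) edges_to_matrix(pop$labels, ei, v)),
    contralesional = lapply(contra[c("count", "FA", "MD")],
                            function(v) edges_to_matrix(pop$labels, ei, v))
  )
  record <- data.frame(
    case_id = case_id,
    sex = sample(c("F", "M"), 1),
    age = sample(20:80, 1),
    side = sample(c("L", "R"), 1),
    pathology = sample(c("GBM", "astrocytoma", "oligodendroglioma"), 1,
                       prob = c(0.55, 0.21, 0.24)),
    grade = sample(c(2L, 3L, 4L), 1, prob = c(0.27, 0.18, 0.55)),
    lobe = lesion$lobe,
    r2 = round(stats::runif(1, 0.58, 0.78), 2),
    stringsAsFactors = FALSE
  )
  list(record = record, matrices = mats, clipped_fraction = ipsi$clipped)
}

#' Generate a synthetic cohort
#'
#' One lesion model per subject; per-subject seeds are derived
#' deterministically from `config$seed`, so the same configuration always
#' yields the same cohort. Contralesional matrices are draws from the
#' baseline model only; ipsilesional matrices differ from baseline only
#' through the lesion effect plus noise.
#'
#' @param config A `generator_config`.
#' @param lesions A single `lesion_model` (recycled) or a list with one
#'   model per subject.
#' @return Object of class `glioma_cohort`: `subjects` (data.frame),
#'   `connectomes` (per case: role -> kind -> matrix), `labels`, and
#'   `ground_truth` (list of the lesion models plus the config).
#' @export
generate_cohort <- function(config, lesions) {
  if (inherits(lesions, "lesion_model")) {
    lesions <- rep(list(lesions), config$n_subjects)
  }
  if (length(lesions) != config$n_subjects) {
    stop("need one lesion model per subject: got ", length(lesions),
         " for ", config$n_subjects, " subjects")
  }
  set.seed(config$seed)
  population <- draw_population(config)
  seeds <- (config$seed + 7919 * seq_len(config$n_subjects)) %% 2147483647L
  subs <- vector("list", config$n_subjects)
  cons <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    cid <- sprintf("S%02d", i)
    g <- generate_subject(config, lesions[[i]], subject_seed = seeds[i],
                          case_id = cid, population = population)
    subs[[i]] <- g$record
    cons[[i]] <- g$matrices
  }
  subjects <- do.call(rbind, subs)
  names(cons) <- subjects$case_id
  structure(list(subjects = subjects, connectomes = cons,
                 labels = population$labels,
                 ground_truth = list(config = config, lesions = lesions)),
            class = "glioma_cohort")
}

#' Write a cohort to disk in the formats the readers accept
#'
#' One TSV per (subject, role, weight kind) plus a metadata CSV and a
#' ground-truth JSON sidecar.
#'
#' @param cohort A `glioma_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  for (cid in cohort$subjects$case_id) {
    for (role in c("ipsilesional", "contralesional")) {
      for (kind in c("count", "FA", "MD")) {
        con <- hemi_connectome(cohort$connectomes[[cid]][[role]][[kind]],
                               weight_kind = kind, role = role, case_id = cid)
        write_connectome(con, file.path(dir, sprintf("%s_%s_%s.tsv",
                                                     cid, role, kind)))
      }
    }
  }
  gt <- cohort$ground_truth
  gt$config$centroids <- NULL
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing subjects.csv and the per-subject TSVs.
#' @return A `glioma_cohort` (without ground truth unless the sidecar exists).
#' @export
read_cohort <- function(dir) {
  subjects <- read_subjects(file.path(dir, "subjects.csv"))
  cons <- list()
  for (cid in subjects$case_id) {
    cons[[cid]] <- list()
    for (role in c("ipsilesional", "contralesional")) {
      cons[[cid]][[role]] <- list()
      for (kind in c("count", "FA", "MD")) {
        f <- file.path(dir, sprintf("%s_%s_%s.tsv", cid, role, kind))
        if (!file.exists(f)) stop("missing matrix file for subject ", cid,
                                  ", ", role, ", ", kind)
        cons[[cid]][[role]][[kind]] <-
          read_connectome(f, weight_kind = kind, role = role, case_id = cid)$matrix
      }
    }
  }
  gt <- NULL
  gtf <- file.path(dir, "ground_truth.json")
  if (file.exists(gtf)) gt <- jsonlite::read_json(gtf)
  structure(list(subjects = subjects, connectomes = cons,
                 labels = atlas_labels(), ground_truth = gt),
            class = "glioma_cohort")
}
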