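#' Construct a hemispheric connectome
#'
#' A hemispheric connectome is one subject x hemisphere x weight-kind
#' 56 x 56 symmetric nonnegative matrix over the atlas node order, holding
#' only intra-hemispheric connections (streamlines crossing the midline are
#' excluded upstream, so no cross-hemisphere edges exist by construction).
#'
#' @param matrix 56 x 56 numeric matrix with dimnames equal to the atlas
#'   labels (any consistent order; reordered to atlas order).
#' @param weight_kind "count" (end-point tract count), "FA" (fractional
#'   anisotropy, values in \[0, 1\]) or "MD" (mean diffusivity on the
#'   1e-3 mm^2/s scale).
#' @param role "ipsilesional" or "contralesional".
#' @param case_id Subject identifier.
#' @param tol Symmetry tolerance.
#' @return An object of class `hemi_connectome`: a list with elements
#'   `case_id`, `role`, `weight_kind`, `labels`, `matrix`.
#' @export
hemi_connectome <- function(matrix, weight_kind, role, case_id = "case",
                            tol = 1e-8) {
  weight_kind <- match.arg(weight_kind, c("count", "FA", "MD"))
  role <- match.arg(role, c("ipsilesional", "contralesional"))
  labels <- atlas_labels()
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(56L, 56L))) {
    stop("connectome matrix must be 56 x 56, got ",
         paste(dim(m), collapse = " x "))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    rownames(m) <- colnames(m) <- labels
  }
  got <- sub("\\.(L|R)$", "", rownames(m))
  if (!setequal(got, labels) || !identical(sub("\\.(L|R)$", "", colnames(m)), got)) {
    bad <- setdiff(got, labels)
    stop("matrix labels do not match the atlas",
         if (length(bad)) paste0("; unknown: ", paste(bad, collapse = ", ")))
  }
  rownames(m) <- colnames(m) <- got
  m <- m[labels, labels]
  if (anyNA(m)) stop("connectome matrix contains NA values")
  asym <- abs(m - t(m))
  if (max(asym) > tol) {
    idx <- which(asym > tol, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    stop("matrix asymmetric beyond tolerance at ",
         paste(utils::head(paste0(labels[idx[, 1]], "-", labels[idx[, 2]]), 5),
               collapse = ", "))
  }
  m <- (m + t(m)) / 2
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative weight at ", labels[idx[1]], "-", labels[idx[2]])
  }
  if (weight_kind == "FA" && any(m > 1)) {
    idx <- which(m > 1, arr.ind = TRUE)[1, ]
    stop("FA weight > 1 at ", labels[idx[1]], "-", labels[idx[2]])
  }
  diag(m) <- 0
  structure(list(case_id = case_id, role = role, weight_kind = weight_kind,
                 labels = labels, matrix = m),
            class = "hemi_connectome")
}

#' @export
print.hemi_connectome <- function(x, ...) {
  cat(sprintf("<hemi_connectome> case %s, %s, %s-weighted: %d nodes, %d edges\n",
              x$case_id, x$role, x$weight_kind, length(x$labels),
              sum(x$matrix[upper.tri(x$matrix)] > 0)))
  invisible(x)
}

#' Read a hemispheric connectome from tab-delimited text
#'
#' Expects a full square matrix: a header row of 56 region labels and a
#' first column of the same labels. Values are validated against the
#' connectome invariants (symmetry, nonnegativity, FA <= 1, zero diagonal).
#'
#' @inheritParams hemi_connectome
#' @param path File to read.
#' @return A `hemi_connectome`.
#' @export
read_connectome <- function(path, weight_kind, role, case_id = "case") {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- labs
  hemi_connectome(m, weight_kind = weight_kind, role = role, case_id = case_id)
}

#' Write a hemispheric connectome as tab-delimited text
#'
#' Serializes the full square matrix at 6 significant digits, the format
#' `read_connectome()` reads back; a write/read cycle is the identity on the
#' serialized values.
#'
#' @param x A `hemi_connectome`.
#' @param path Output file.
#' @export
write_connectome <- function(x, path) {
  stopifnot(inherits(x, "hemi_connectome"))
  m <- signif(x$matrix, 6)
  df <- data.frame(node = x$labels, m, check.names = FALSE)
  colnames(df) <- c("node", x$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' CSV with columns case_id, sex, age, side, pathology, grade, lobe, r2.
#' Validates the unilateral-design invariants (r2 in \[0, 1\], age > 0,
#' single lesion side and lobe per subject).
#'
#' @param path CSV file. Defaults to the packaged 33-subject glioma cohort
#'   table (22 frontal, 5 parietal, 6 temporal).
#' @return data.frame of subject records.
#' @export
read_subjects <- function(path = NULL) {
  if (is.null(path)) path <- pkg_file("extdata", "glioma_cohort_demographics.csv")
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(case_id = "character"))
  need <- c("case_id", "sex", "age", "side", "pathology", "grade", "lobe", "r2")
  if (!all(need %in% names(d))) {
    stop("subject table missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  stopifnot(all(d$r2 >= 0 & d$r2 <= 1), all(d$age > 0),
            all(d$sex %in% c("F", "M")), all(d$side %in% c("L", "R")))
  d
}

#' Read a published group-level connection table
#'
#' The package bundles the reported connection screens for the frontal,
#' parietal and temporal lesion groups of a 33-subject glioma cohort (edges
#' whose ipsilesional mean end-point tract count fell outside the
#' contralesional 95% CI, with FA/MD follow-up values where those were also
#' significant). These serve as worked examples for the lobe-composition
#' summaries.
#'
#' @param group "frontal", "parietal" or "temporal".
#' @return data.frame with columns node_a, node_b, direction, count_change,
#'   fa_contra, fa_ipsi, fa_sig, md_contra, md_ipsi, md_sig.
#' @export
read_edge_table <- function(group = c("frontal", "parietal", "temporal")) {
  group <- match.arg(group)
  path <- pkg_file("extdata", paste0("edges_", group, "_group.tsv"))
  utils::read.delim(path, stringsAsFactors = FALSE)
}
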