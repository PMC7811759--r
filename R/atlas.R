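#' AAL2 hemispheric atlas (56 regions per hemisphere, vermis excluded)
#'
#' Returns the packaged node lookup used by every matrix in the pipeline:
#' 112 regions (56 per hemisphere), each with a lobe category drawn from
#' \{frontal, parietal, temporal, occipital, limbic, central, subcortical,
#' cerebellum\} and an approximate MNI-space centroid. Left-hemisphere
#' centroids are tabulated; right-hemisphere centroids are the mirror image
#' (x negated). Lobe assignments for regions that appear in the published
#' connection tables follow the categories used there (e.g. insula and
#' mid-cingulate are limbic, fusiform is grouped with occipital, Rolandic
#' operculum and postcentral gyrus are central); assignments for the
#' remaining regions are conventional AAL2 groupings and should be treated
#' as non-authoritative. Centroid coordinates are plausible atlas-scale
#' values used only for synthetic lesion placement and distance analysis.
#'
#' @return A data.frame with columns `label`, `long_name`, `hemisphere`
#'   ("L"/"R"), `lobe`, `index` (0-based position within the hemisphere),
#'   `x`, `y`, `z` (mm). Row order is the fixed node order shared by all
#'   connectivity matrices: the 56 left regions, then the 56 right regions.
#' @export
load_atlas <- function() {
  if (!is.null(.cache$atlas)) return(.cache$atlas)
  path <- pkg_file("extdata", "aal2_regions.tsv")
  base <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "long_name", "lobe", "x", "y", "z")
  if (!all(need %in% names(base)) || nrow(base) != 56 ||
      anyDuplicated(base$label) > 0) {
    stop("packaged atlas table is corrupted: expected 56 unique regions ",
         "with columns ", paste(need, collapse = ", "))
  }
  lobes <- c("frontal", "parietal", "temporal", "occipital", "limbic",
             "central", "subcortical", "cerebellum")
  if (!all(base$lobe %in% lobes)) {
    stop("packaged atlas table is corrupted: unknown lobe category")
  }
  left <- cbind(base[, c("label", "long_name")], hemisphere = "L",
                lobe = base$lobe, index = seq_len(56) - 1L,
                base[, c("x", "y", "z")])
  right <- left
  right$hemisphere <- "R"
  right$x <- -right$x
  out <- rbind(left, right)
  rownames(out) <- NULL
  .cache$atlas <- out
  out
}

.cache <- new.env(parent = emptyenv())

pkg_file <- function(...) {
  p <- system.file(..., package = "hemiconn")
  if (!nzchar(p)) stop("packaged file not found: ", file.path(...))
  p
}

#' Lobe category of an AAL2 region
#'
#' @param label Character vector of AAL2 region labels. A hemisphere suffix
#'   (".L"/".R") is tolerated and stripped before lookup.
#' @return Character vector of lobe categories.
#' @examples
#' lobe_of(c("SFG", "INS", "FFG", "PoCG", "CB9"))
#' @export
lobe_of <- function(label) {
  atlas <- load_atlas()
  bare <- sub("\\.(L|R)$", "", label)
  idx <- match(bare, atlas$label[atlas$hemisphere == "L"])
  if (anyNA(idx)) {
    stop("unknown atlas label(s): ",
         paste(unique(bare[is.na(idx)]), collapse = ", "))
  }
  atlas$lobe[atlas$hemisphere == "L"][idx]
}

#' Node centroid table for one hemisphere
#'
#' @param hemisphere "L" (default) or "R".
#' @return 56 x 3 numeric matrix of centroid coordinates (mm), rownames are
#'   region labels in atlas order.
#' @export
node_centroids <- function(hemisphere = "L") {
  hemisphere <- match.arg(hemisphere, c("L", "R"))
  atlas <- load_atlas()
  a <- atlas[atlas$hemisphere == hemisphere, ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$label
  m
}

#' Atlas node labels in canonical order
#' @return Character vector of the 56 region labels (one hemisphere).
#' @export
atlas_labels <- function() {
  atlas <- load_atlas()
  atlas$label[atlas$hemisphere == "L"]
}
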