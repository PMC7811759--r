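#' Summarize a glioma cohort
#'
#' Recomputes the demographic and registration summaries: age mean/SD/range,
#' sex, pathology and WHO-grade counts with percentages, and registration R^2
#' mean/SD/range, overall and within each lesion-lobe subgroup. Standard
#' deviations use the sample (n - 1) denominator; with a single record the
#' SD is reported as NA. Percentages are 100 * count / n rounded to the
#' nearest integer (halves away from zero).
#'
#' @param records data.frame of subject records as returned by
#'   [read_subjects()].
#' @return A list of class `cohort_summary` with an `overall` element and a
#'   `by_lobe` list of the same shape per lesion lobe.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("need at least one subject record")
  }
  one <- function(d) {
    n <- nrow(d)
    counts <- function(x, lev = sort(unique(x))) {
      vapply(stats::setNames(as.character(lev), lev),
             function(l) sum(as.character(x) == l), integer(1))
    }
    pct <- function(cnt) round_half_up(100 * cnt / n)
    sdn <- function(x) if (n > 1) stats::sd(x) else NA_real_
    sx <- counts(d$sex, c("F", "M"))
    pa <- counts(d$pathology)
    gr <- counts(d$grade, c(2, 3, 4))
    list(
      n = n,
      mean_age = mean(d$age), sd_age = sdn(d$age),
      min_age = min(d$age), max_age = max(d$age),
      sex_counts = sx, sex_pct = pct(sx),
      pathology_counts = pa, pathology_pct = pct(pa),
      grade_counts = gr, grade_pct = pct(gr),
      mean_r2 = mean(d$r2), sd_r2 = sdn(d$r2),
      min_r2 = min(d$r2), max_r2 = max(d$r2)
    )
  }
  out <- list(overall = one(records),
              by_lobe = lapply(split(records, records$lobe), one))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("Cohort: n = %d; age %.2f (SD %s; range %d-%d)\n", o$n,
              o$mean_age, if (is.na(o$sd_age)) "NA" else sprintf("%.2f", o$sd_age),
              o$min_age, o$max_age))
  cat(sprintf("Sex: %s\n", paste(sprintf("%s %d (%d%%)", names(o$sex_counts),
                                         o$sex_counts, o$sex_pct), collapse = ", ")))
  cat(sprintf("Pathology: %s\n",
              paste(sprintf("%s %d (%d%%)", names(o$pathology_counts),
                            o$pathology_counts, o$pathology_pct), collapse = ", ")))
  cat(sprintf("WHO grade: %s\n", paste(sprintf("%s: %d (%d%%)",
                                               names(o$grade_counts),
                                               o$grade_counts, o$grade_pct),
                                       collapse = ", ")))
  cat(sprintf("Registration R^2: %.2f (SD %s; range %.2f-%.2f)\n", o$mean_r2,
              if (is.na(o$sd_r2)) "NA" else sprintf("%.2f", o$sd_r2),
              o$min_r2, o$max_r2))
  for (lb in names(x$by_lobe)) {
    s <- x$by_lobe[[lb]]
    cat(sprintf("  %s: n = %d, age %.2f (SD %s)\n", lb, s$n, s$mean_age,
                if (is.na(s$sd_age)) "NA" else sprintf("%.2f", s$sd_age)))
  }
  invisible(x)
}

# nearest-integer percentage with halves away from zero (printed-table style)
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}
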