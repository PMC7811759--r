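#' Log-normalize a vector of nodal values
#'
#' Natural log of the strictly positive values; nonpositive values and NAs
#' are dropped and counted (nodal measures are nonnegative with heavy right
#' tails, so the log is taken without an offset).
#'
#' @param values Numeric vector, NAs allowed.
#' @return List with `values` (log-transformed) and `n_dropped`.
#' @export
log_normalize <- function(values) {
  keep <- !is.na(values) & values > 0
  if (!any(keep)) stop("no positive values to log-normalize")
  list(values = log(values[keep]), n_dropped = sum(!keep))
}

#' Remove outliers by the boxplot (Tukey) rule
#'
#' Drops values outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] with quartiles by
#' linear interpolation (R quantile type 7). With fewer than 4 values the
#' input is passed through with a warning.
#'
#' @param values Numeric vector (no NAs).
#' @return List with `values` (retained) and `n_removed`.
#' @export
remove_outliers <- function(values) {
  if (length(values) < 4) {
    warning("fewer than 4 values; outlier screen skipped")
    return(list(values = values, n_removed = 0L))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
  list(values = values[keep], n_removed = sum(!keep))
}

#' Normality screen (Anderson-Darling and skewness-kurtosis)
#'
#' Informational only: the pipeline always proceeds nonparametrically, the
#' screen documents why. The skewness-kurtosis test is the Jarque-Bera
#' omnibus statistic n/6 (S^2 + (K - 3)^2 / 4) against chi-square(2).
#'
#' @param values Numeric vector; needs >= 8 finite values.
#' @return data.frame with rows `anderson_darling` and `skew_kurtosis`
#'   (columns statistic, p_value); NAs with a warning when degenerate or too
#'   short.
#' @export
normality_screen <- function(values) {
  values <- values[is.finite(values)]
  na_out <- data.frame(test = c("anderson_darling", "skew_kurtosis"),
                       statistic = NA_real_, p_value = NA_real_)
  if (length(values) < 8) {
    warning("fewer than 8 values; normality screen not run")
    return(na_out)
  }
  if (stats::sd(values) == 0) {
    warning("constant vector; normality screen degenerate")
    return(na_out)
  }
  ad <- nortest::ad.test(values)
  n <- length(values)
  z <- (values - mean(values)) / sqrt(mean((values - mean(values))^2))
  s <- mean(z^3)
  k <- mean(z^4)
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  data.frame(test = c("anderson_darling", "skew_kurtosis"),
             statistic = c(unname(ad$statistic), jb),
             p_value = c(ad$p.value, stats::pchisq(jb, df = 2,
                                                   lower.tail = FALSE)))
}

#' Hemispheric Wilcoxon comparison of nodal measures
#'
#' For each of the 12 (weight kind x measure) combinations: build the
#' ipsilesional and contralesional samples, log-normalize, remove boxplot
#' outliers, run a two-sample Wilcoxon rank-sum test, and adjust the 12
#' p-values with Benjamini-Hochberg. `pooling = "subject_mean"` (default)
#' uses one hemispheric mean per subject per role, i.e. 2 x n_subjects
#' sample points per test; `"pooled_nodes"` pools all nodal values
#' (n_subjects x 56 per role).
#'
#' @param metrics data.frame from [compute_nodal_metrics()].
#' @param pooling "subject_mean" or "pooled_nodes".
#' @param alpha Significance level on the adjusted p-value.
#' @return data.frame with one row per (weight_kind, metric): sample sizes
#'   after cleaning, raw and BH-adjusted p, direction of the ipsilesional
#'   shift ("increase"/"decrease"/"none"), and drop/outlier counts.
#' @export
hemispheric_test <- function(metrics,
                             pooling = c("subject_mean", "pooled_nodes"),
                             alpha = 0.05) {
  pooling <- match.arg(pooling)
  if (!all(c("ipsilesional", "contralesional") %in% metrics$role)) {
    stop("metric table must contain both ipsilesional and contralesional rows")
  }
  kinds <- c("count", "FA", "MD")
  meas <- c("cc", "le", "bc", "ec")
  rows <- list()
  for (kind in kinds) {
    for (ms in meas) {
      sub <- metrics[metrics$weight_kind == kind, c("case_id", "role", ms)]
      samp <- function(role) {
        v <- sub[sub$role == role, ]
        if (pooling == "subject_mean") {
          tapply(v[[ms]], v$case_id, mean, na.rm = TRUE)
        } else {
          v[[ms]]
        }
      }
      clean <- function(x) {
        lg <- log_normalize(as.numeric(x))
        ol <- remove_outliers(lg$values)
        list(values = ol$values, n_dropped = lg$n_dropped,
             n_outliers = ol$n_removed)
      }
      ips <- clean(samp("ipsilesional"))
      con <- clean(samp("contralesional"))
      p <- if (length(unique(c(ips$values, con$values))) == 1) {
        1
      } else {
        suppressWarnings(stats::wilcox.test(ips$values, con$values,
                                            exact = NULL)$p.value)
      }
      rows[[paste(kind, ms)]] <- data.frame(
        weight_kind = kind, metric = ms,
        n_ipsi = length(ips$values), n_contra = length(con$values),
        median_ipsi = stats::median(ips$values),
        median_contra = stats::median(con$values),
        p_value = p,
        n_dropped_ipsi = ips$n_dropped, n_dropped_contra = con$n_dropped,
        n_outliers_ipsi = ips$n_outliers, n_outliers_contra = con$n_outliers
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$direction <- ifelse(out$p_adjusted < alpha,
                          ifelse(out$median_ipsi > out$median_contra,
                                 "increase", "decrease"),
                          "none")
  out
}
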