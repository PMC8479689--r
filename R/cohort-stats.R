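#' Descriptive summary of a cohort metric
#'
#' Sample mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum of a metric across a cohort.
#'
#' @param values Numeric vector; `NA`s are dropped; at least two values
#'   must remain.
#' @return A list with `n`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_cohort <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("insufficient data: need at least 2 values", call. = FALSE)
  list(n = length(values), mean = mean(values), sd = stats::sd(values),
       min = min(values), max = max(values))
}

#' Two-sample t test (pooled or Welch)
#'
#' Two-sided two-sample t test between two cohorts' metric values: the
#' pooled-variance test (df = na + nb - 2) when `equal_variance` is `TRUE`,
#' Welch's test with Welch-Satterthwaite df otherwise. When both samples
#' have zero variance, the test is defined by convention: p = 1 (t = 0) if
#' the means are equal, p = 0 otherwise, rather than an error.
#'
#' @param a,b Numeric vectors, each with at least two values after
#'   dropping `NA`s.
#' @param equal_variance Use the pooled-variance statistic?
#' @return A list with `t`, `df`, `p`, and `method`.
#' @export
two_sample_ttest <- function(a, b, equal_variance = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  method <- if (equal_variance) "pooled" else "welch"
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L,
                p = if (same) 1 else 0, method = method))
  }
  tt <- stats::t.test(a, b, var.equal = equal_variance)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, method = method)
}

#' Compare two cohorts metric by metric
#'
#' Runs both t-test variants (pooled and Welch) for each named metric
#' column of two per-cell metric tables and flags significance at the 0.05
#' and 0.01 levels. A metric is flagged significant only when both
#' variants fall below the level.
#'
#' @param metrics_a,metrics_b Per-cell metric tables (see
#'   [cell_metrics()]), e.g. one per cohort.
#' @param metric_names Character vector of metric columns to compare;
#'   defaults to the elasticity metrics present in both tables.
#' @return A data frame with one row per metric: `metric`, `t_pooled`,
#'   `df_pooled`, `p_pooled`, `t_welch`, `df_welch`, `p_welch`,
#'   `significant_at_0p05`, `significant_at_0p01`.
#' @export
compare_cohorts <- function(metrics_a, metrics_b,
                            metric_names = NULL) {
  if (!is.data.frame(metrics_a) || !is.data.frame(metrics_b) ||
      nrow(metrics_a) == 0L || nrow(metrics_b) == 0L)
    stop("metric tables must be nonempty data frames", call. = FALSE)
  if (is.null(metric_names)) {
    candidates <- c("pct_dr_free", "pct_dr_stretch", "pct_da_free",
                    "pct_da_stretch", "stiffness_uN_m",
                    "axis_ratio_stretched", "free_rmax_um",
                    "trap_force_pN", "drag_force_pN")
    metric_names <- intersect(candidates,
                              intersect(names(metrics_a), names(metrics_b)))
  }
  missing <- setdiff(metric_names,
                     intersect(names(metrics_a), names(metrics_b)))
  if (length(missing))
    stop("metric(s) missing from a table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- lapply(metric_names, function(m) {
    pooled <- two_sample_ttest(metrics_a[[m]], metrics_b[[m]],
                               equal_variance = TRUE)
    welch <- two_sample_ttest(metrics_a[[m]], metrics_b[[m]],
                              equal_variance = FALSE)
    data.frame(metric = m,
               t_pooled = pooled$t, df_pooled = pooled$df,
               p_pooled = pooled$p,
               t_welch = welch$t, df_welch = welch$df, p_welch = welch$p,
               significant_at_0p05 = pooled$p < 0.05 && welch$p < 0.05,
               significant_at_0p01 = pooled$p < 0.01 && welch$p < 0.01,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
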