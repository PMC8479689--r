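#' Fit a two-cohort RBC elasticity analysis
#'
#' The front door of the package: takes a table of per-cell optical-tweezer
#' records (two cohorts, e.g. sickle-trait HbAS and sickle-anemia HbSS),
#' computes every per-cell elasticity metric (percent differences in radius
#' and area relative to the trapped state, stiffness k = dF/dR, axis
#' ratios), optionally applies sort-and-delete trimming recipes, and
#' produces per-cohort descriptive statistics plus pooled and Welch
#' two-sample t tests for each metric.
#'
#' @param records A cell-record data frame (schema in [read_records()])
#'   containing one or two cohorts in its `cohort` column.
#' @param trim `NULL` (no trimming), or a named list mapping cohort labels
#'   to [trim_recipe()]s or built-in recipe names (see
#'   [builtin_trim_recipes()]).
#' @param stiffness_force,radius Passed to [cell_metrics()].
#' @param metrics Metric columns to compare between cohorts; default the
#'   standard elasticity set.
#' @return An object of class `"rbc_elasticity"` with components
#'   `metrics` (named list of per-cohort metric tables, after trimming),
#'   `summaries` (long data frame of per-cohort descriptive statistics),
#'   `comparison` (from [compare_cohorts()]; `NULL` for a single cohort),
#'   `trim_audit` (named list of trimming audit logs), `cohorts`, and
#'   `call`. Methods: `print`, `summary`, `coef`, `plot`, `simulate`.
#' @examples
#' cfgs <- default_cohort_configs()
#' recs <- rbind(generate_elasticity_cohort(cfgs$hbas, seed = 1)$records,
#'               generate_elasticity_cohort(cfgs$hbss, seed = 2)$records)
#' fit <- rbc_elasticity(recs)
#' coef(fit)
#' @export
rbc_elasticity <- function(records, trim = NULL,
                           stiffness_force = c("net", "drag"),
                           radius = c("r_max", "r_equiv"),
                           metrics = c("pct_dr_free", "pct_dr_stretch",
                                       "pct_da_free", "pct_da_stretch",
                                       "stiffness_uN_m", "free_rmax_um",
                                       "trap_force_pN", "drag_force_pN")) {
  validate_records(records)
  cohorts <- unique(records$cohort)
  if (length(cohorts) > 2L)
    stop("records contain more than two cohorts: ",
         paste(cohorts, collapse = ", "), call. = FALSE)
  per_cohort <- lapply(cohorts, function(ch) {
    cell_metrics(records[records$cohort == ch, , drop = FALSE],
                 stiffness_force = stiffness_force, radius = radius)
  })
  names(per_cohort) <- cohorts
  audits <- stats::setNames(vector("list", length(cohorts)), cohorts)
  if (!is.null(trim)) {
    if (is.null(names(trim)))
      stop("`trim` must be a named list keyed by cohort label",
           call. = FALSE)
    for (ch in names(trim)) {
      if (!ch %in% cohorts)
        stop("trim recipe given for unknown cohort `", ch, "`",
             call. = FALSE)
      res <- apply_recipe(per_cohort[[ch]], trim[[ch]])
      per_cohort[[ch]] <- res$metrics
      audits[[ch]] <- res$audit
    }
  }
  summaries <- do.call(rbind, lapply(cohorts, function(ch) {
    tab <- per_cohort[[ch]]
    do.call(rbind, lapply(metrics, function(m) {
      v <- tab[[m]]
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(NULL)
      s <- summarize_cohort(v)
      data.frame(cohort = ch, metric = m, n = s$n, mean = s$mean,
                 sd = s$sd, min = s$min, max = s$max,
                 stringsAsFactors = FALSE)
    }))
  }))
  comparison <- if (length(cohorts) == 2L)
    compare_cohorts(per_cohort[[1L]], per_cohort[[2L]],
                    intersect(metrics, names(per_cohort[[1L]])))
  else NULL
  structure(list(metrics = per_cohort, summaries = summaries,
                 comparison = comparison, trim_audit = audits,
                 cohorts = cohorts, call = match.call()),
            class = "rbc_elasticity")
}

#' @export
print.rbc_elasticity <- function(x, ...) {
  cat("RBC optical-tweezer elasticity analysis\n")
  for (ch in x$cohorts)
    cat(sprintf("  cohort %s: %d cells%s\n", ch, nrow(x$metrics[[ch]]),
                if (!is.null(x$trim_audit[[ch]]))
                  sprintf(" (%d trimmed)", nrow(x$trim_audit[[ch]]))
                else ""))
  if (!is.null(x$comparison)) {
    sig <- x$comparison$metric[x$comparison$significant_at_0p05]
    cat("  metrics differing at the 0.05 level (both t-test variants): ",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n",
        sep = "")
  }
  invisible(x)
}

#' Summarise an RBC elasticity analysis
#'
#' @param object An [rbc_elasticity()] fit.
#' @param ... Unused.
#' @return The object, invisibly; prints the per-cohort descriptive table
#'   and the per-metric t-test comparison.
#' @export
summary.rbc_elasticity <- function(object, ...) {
  cat("Per-cohort descriptive statistics:\n")
  print(object$summaries, row.names = FALSE, digits = 4)
  if (!is.null(object$comparison)) {
    cat("\nTwo-sample t tests (", paste(object$cohorts, collapse = " vs "),
        "):\n", sep = "")
    print(object$comparison, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Cohort mean metrics of an elasticity fit
#'
#' @param object An [rbc_elasticity()] fit.
#' @param ... Unused.
#' @return A matrix of cohort means: metrics in rows, cohorts in columns.
#' @export
coef.rbc_elasticity <- function(object, ...) {
  s <- object$summaries
  mets <- unique(s$metric)
  out <- matrix(unlist(lapply(object$cohorts, function(ch) {
    sub <- s[s$cohort == ch, ]
    sub$mean[match(mets, sub$metric)]
  })), nrow = length(mets),
  dimnames = list(mets, object$cohorts))
  out
}

#' Plot an RBC elasticity analysis
#'
#' Side-by-side cohort boxplots of the radius percent difference and
#' stiffness, and a stiffness-versus-radius scatter, in the style of the
#' published comparison figures.
#'
#' @param x An [rbc_elasticity()] fit.
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.rbc_elasticity <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  pull <- function(col) lapply(x$metrics, `[[`, col)
  graphics::boxplot(pull("pct_dr_free"), ylab = "%DR (free vs trapped)",
                    main = "Radius percent difference", ...)
  graphics::boxplot(pull("stiffness_uN_m"), ylab = "k (uN/m)",
                    main = "Stiffness", ...)
  cols <- seq_along(x$cohorts) + 1L
  rad <- pull("free_rmax_um"); stf <- pull("stiffness_uN_m")
  graphics::plot(NA, xlim = range(unlist(rad), na.rm = TRUE),
                 ylim = range(unlist(stf), na.rm = TRUE),
                 xlab = "free r_max (um)", ylab = "k (uN/m)",
                 main = "Stiffness vs radius")
  for (i in seq_along(x$cohorts))
    graphics::points(rad[[i]], stf[[i]], col = cols[i], pch = 19)
  graphics::legend("topleft", legend = x$cohorts, col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}

#' Simulate synthetic cohorts matching a fitted analysis
#'
#' Builds elasticity-mode [cohort_config()]s whose location parameters are
#' the fitted cohort means (free radius and its observed range, trap and
#' drag forces, stiffness, trapped-state compression) and generates new
#' synthetic cohorts from them — a parametric-bootstrap-style check that
#' the generator and the analysis invert each other.
#'
#' @param object An [rbc_elasticity()] fit of elasticity records.
#' @param nsim Number of replicate record tables.
#' @param seed Integer seed; replicate i uses `seed + i - 1`.
#' @param n_cells Cells per cohort in each replicate (divisible by 7).
#' @param ... Unused.
#' @return A list of `nsim` record data frames, each holding both
#'   simulated cohorts.
#' @export
simulate.rbc_elasticity <- function(object, nsim = 1, seed = 1L,
                                    n_cells = 49L, ...) {
  s <- object$summaries
  grab <- function(ch, m, what = "mean") {
    sub <- s[s$cohort == ch & s$metric == m, ]
    if (nrow(sub) == 0L)
      stop("metric `", m, "` unavailable for cohort `", ch,
           "`; cannot simulate", call. = FALSE)
    sub[[what]]
  }
  cfgs <- lapply(object$cohorts, function(ch) {
    rmin <- grab(ch, "free_rmax_um", "min")
    rmax <- grab(ch, "free_rmax_um", "max")
    cohort_config(
      ch, "elasticity", n_cells = n_cells,
      radius_mean = grab(ch, "free_rmax_um"),
      radius_range = c(rmin - 1e-9, rmax + 1e-9),
      trap_force_mean = grab(ch, "trap_force_pN"),
      drag_force_mean = grab(ch, "drag_force_pN"),
      stiffness_mean = grab(ch, "stiffness_uN_m"),
      trap_compression_mean = grab(ch, "pct_dr_free"))
  })
  lapply(seq_len(nsim), function(i) {
    do.call(rbind, lapply(cfgs, function(cfg)
      generate_elasticity_cohort(cfg, seed = seed + i - 1L)$records))
  })
}
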