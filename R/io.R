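#' Read and write cell-record tables
#'
#' The CSV record schema has one row per cell with explicit units in the
#' column names: `cell_id`, `cohort`, `subgroup`, `stage_speed_um_s`,
#' `trap_force_pN`, `drag_force_pN`, and for each of the three states
#' (`free`, `trapped`, `stretched`) the columns `*_rmax_um`, `*_rmin_um`,
#' `*_area_um2`. Missing stretched measurements are empty/NA.
#'
#' @param path CSV file path.
#' @param records A record data frame (e.g. from
#'   [generate_elasticity_cohort()]'s `$records`).
#' @return `read_records` returns the typed record data frame (possibly
#'   zero rows); `write_records` returns `path` invisibly.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  missing <- setdiff(record_columns(), names(raw))
  if (length(missing))
    stop("schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(record_columns(), c("cell_id", "cohort"))
  out <- raw[record_columns()]
  for (col in num_cols) {
    v <- trimws(out[[col]])
    v[v == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "NA" & is.na(parsed))
    if (length(bad))
      stop(sprintf("parse error at row %d, column `%s`: %s",
                   bad[1L], col, v[bad[1L]]), call. = FALSE)
    out[[col]] <- parsed
  }
  out$subgroup <- as.integer(out$subgroup)
  out
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  validate_records(records)
  utils::write.csv(records[record_columns()], path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a cohort-comparison report as JSON
#'
#' Emits a versioned JSON report holding per-metric comparison results and
#' per-cohort descriptive summaries, plus the seed and a hash of the
#' configuration used, so two runs with the same inputs produce identical
#' files.
#'
#' @param comparisons A comparison table from [compare_cohorts()] (may
#'   have zero rows).
#' @param summaries A data frame of cohort summaries (e.g. from
#'   [summary.rbc_elasticity()]), or `NULL`.
#' @param path Output path.
#' @param seed Integer seed recorded in the report.
#' @param config Any R object describing the run configuration; hashed
#'   into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(comparisons, summaries = NULL, path,
                         seed = NA_integer_, config = NULL) {
  if (!is.data.frame(comparisons))
    stop("`comparisons` must be a data frame", call. = FALSE)
  report <- list(
    schema_version = "1.0",
    seed = seed,
    config_hash = config_hash(config),
    comparisons = comparisons,
    summaries = summaries)
  ok <- tryCatch({
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("could not write report to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Read a run configuration from YAML
#'
#' Parses a YAML run configuration with optional blocks `optics`
#' (`power_mW`, `beam_waist_um`, `n_medium`, `index_ratio`,
#' `wavelength_nm`), `fluid` (`viscosity_mPa_s`, `shape_factor`),
#' `cohorts` (a named list of [cohort_config()] argument lists), `recipes`
#' (named lists of `{key, n_low, n_high}` steps) and a top-level `seed`.
#' Interface units are the laboratory ones (mW, um, mPa s); they are
#' converted to SI on construction.
#'
#' @param path YAML file path.
#' @return A list of class `"run_config"` with elements `optics`, `fluid`,
#'   `cohorts`, `recipes`, `seed` (absent blocks are `NULL` or defaults).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  optics <- NULL
  if (!is.null(y$optics)) {
    o <- y$optics
    optics <- optical_config(
      power = o$power_mW * 1e-3,
      beam_waist = o$beam_waist_um * 1e-6,
      n_medium = if (is.null(o$n_medium)) 1.334 else o$n_medium,
      index_ratio = if (is.null(o$index_ratio)) 1.05 else o$index_ratio,
      wavelength = if (is.null(o$wavelength_nm)) 1064e-9
                   else o$wavelength_nm * 1e-9)
  }
  fluid <- fluid_config()
  if (!is.null(y$fluid))
    fluid <- fluid_config(
      viscosity = if (is.null(y$fluid$viscosity_mPa_s)) 1.0e-3
                  else y$fluid$viscosity_mPa_s * 1e-3,
      shape_factor = if (is.null(y$fluid$shape_factor)) 1.0
                     else y$fluid$shape_factor)
  cohorts <- NULL
  if (!is.null(y$cohorts))
    cohorts <- lapply(y$cohorts, function(args) {
      args$fluid <- fluid
      do.call(cohort_config, args)
    })
  recipes <- NULL
  if (!is.null(y$recipes))
    recipes <- lapply(names(y$recipes), function(nm) {
      steps <- lapply(y$recipes[[nm]], function(s)
        trim_step(s$key,
                  n_low = if (is.null(s$n_low)) 0L else s$n_low,
                  n_high = if (is.null(s$n_high)) 0L else s$n_high))
      trim_recipe(nm, steps)
    })
  if (!is.null(recipes)) names(recipes) <- names(y$recipes)
  structure(list(optics = optics, fluid = fluid, cohorts = cohorts,
                 recipes = recipes,
                 seed = if (is.null(y$seed)) 1L else as.integer(y$seed)),
            class = "run_config")
}
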