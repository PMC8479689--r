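# metric-key -> column of the cell_metrics table
trim_key_columns <- c(
  trap_force = "trap_force_pN",
  drag_force = "drag_force_pN",
  radius = "free_rmax_um",
  pct_da = "pct_da_free",
  axis_ratio = "axis_ratio_stretched",
  stiffness = "stiffness_uN_m",
  delta_radius = "delta_radius_um")

#' One sort-and-delete trimming step
#'
#' A data-reduction step of the kind applied to the published scatter data
#' before plotting: sort the per-cell metric table by one metric and delete
#' a fixed number of cells from each extreme.
#'
#' @param key Metric to sort by; one of
#'   `r paste0('\x60', names(trim_key_columns), '\x60', collapse = ", ")`.
#' @param n_low Number of cells removed from the minimum end (>= 0).
#' @param n_high Number removed from the maximum end (>= 0).
#' @return An object of class `"trim_step"`.
#' @export
trim_step <- function(key, n_low = 0L, n_high = 0L) {
  if (!is.character(key) || length(key) != 1L ||
      !key %in% names(trim_key_columns))
    stop("unknown trim key: ", paste(key, collapse = ", "),
         "; valid keys: ", paste(names(trim_key_columns), collapse = ", "),
         call. = FALSE)
  n_low <- as.integer(n_low); n_high <- as.integer(n_high)
  if (is.na(n_low) || is.na(n_high) || n_low < 0L || n_high < 0L)
    stop("`n_low` and `n_high` must be >= 0", call. = FALSE)
  structure(list(key = key, n_low = n_low, n_high = n_high),
            class = "trim_step")
}

#' An ordered trimming recipe
#'
#' @param name Recipe label.
#' @param steps List of [trim_step()]s, applied in order; may be empty
#'   (identity recipe).
#' @return An object of class `"trim_recipe"`.
#' @seealso [builtin_trim_recipes()] for the published recipes.
#' @export
trim_recipe <- function(name, steps = list()) {
  if (!is.list(steps) ||
      !all(vapply(steps, inherits, logical(1), "trim_step")))
    stop("`steps` must be a list of trim_step objects", call. = FALSE)
  structure(list(name = name, steps = steps), class = "trim_recipe")
}

#' Built-in data-reduction recipes
#'
#' The sort-and-delete sequences used on the published 49-cell cohorts
#' before the radius/area percent-difference figures were drawn. The HbSS
#' recipe removes 2 minima + 1 maximum by trap force, then 2 minima + 2
#' maxima by radius, then 1 minimum + 3 maxima by area percent difference
#' (11 cells in total); the HbAS recipe removes 2 + 2 by trap force, 1
#' minimum + 2 maxima by radius, then 3 maxima by area percent difference
#' (10 cells).
#'
#' @return A named list of [trim_recipe()]s: `hbss_fig6`, `hbas_fig6`.
#' @export
builtin_trim_recipes <- function() {
  list(
    hbss_fig6 = trim_recipe("hbss_fig6", list(
      trim_step("trap_force", n_low = 2L, n_high = 1L),
      trim_step("radius", n_low = 2L, n_high = 2L),
      trim_step("pct_da", n_low = 1L, n_high = 3L))),
    hbas_fig6 = trim_recipe("hbas_fig6", list(
      trim_step("trap_force", n_low = 2L, n_high = 2L),
      trim_step("radius", n_low = 1L, n_high = 2L),
      trim_step("pct_da", n_low = 0L, n_high = 3L))))
}

#' Trim the extremes of a metric table
#'
#' Sorts the table ascending by the step's metric (ties broken by
#' `cell_id`, so the removal set is independent of input order), removes
#' `n_low` cells from the minimum end and `n_high` from the maximum end,
#' and returns the remaining rows in their original input order.
#'
#' @param metrics A per-cell metric table from [cell_metrics()].
#' @param step A [trim_step()].
#' @return The trimmed table, with the removed `cell_id`s in attribute
#'   `"removed"`.
#' @export
trim_extremes <- function(metrics, step) {
  stopifnot(inherits(step, "trim_step"))
  col <- trim_key_columns[[step$key]]
  if (!col %in% names(metrics))
    stop("metric column `", col, "` not found", call. = FALSE)
  n <- nrow(metrics)
  n_rm <- step$n_low + step$n_high
  if (n <= n_rm)
    stop(sprintf("insufficient data: %d records, %d removals requested",
                 n, n_rm), call. = FALSE)
  ord <- order(metrics[[col]], metrics$cell_id)
  drop <- integer(0)
  if (step$n_low > 0L) drop <- c(drop, ord[seq_len(step$n_low)])
  if (step$n_high > 0L) drop <- c(drop, ord[n - seq_len(step$n_high) + 1L])
  out <- if (length(drop)) metrics[-drop, , drop = FALSE] else metrics
  attr(out, "removed") <- metrics$cell_id[sort(drop)]
  out
}

#' Apply a trimming recipe
#'
#' Applies the steps of a recipe sequentially and records which cells each
#' step removed.
#'
#' @param metrics A per-cell metric table from [cell_metrics()].
#' @param recipe A [trim_recipe()], or the name of a built-in recipe.
#' @return A list: `metrics` (the trimmed table) and `audit`, a data frame
#'   with columns `step`, `key`, `cell_id` listing every removal in order.
#' @export
apply_recipe <- function(metrics, recipe) {
  if (is.character(recipe)) {
    recipes <- builtin_trim_recipes()
    if (!recipe %in% names(recipes))
      stop("unknown recipe `", recipe, "`; built-ins: ",
           paste(names(recipes), collapse = ", "), call. = FALSE)
    recipe <- recipes[[recipe]]
  }
  stopifnot(inherits(recipe, "trim_recipe"))
  audit <- data.frame(step = integer(0), key = character(0),
                      cell_id = character(0), stringsAsFactors = FALSE)
  out <- metrics
  for (i in seq_along(recipe$steps)) {
    st <- recipe$steps[[i]]
    out <- tryCatch(trim_extremes(out, st), error = function(e) {
      stop(sprintf("recipe `%s` failed at step %d (%s): %s",
                   recipe$name, i, st$key, conditionMessage(e)),
           call. = FALSE)
    })
    rem <- attr(out, "removed")
    if (length(rem))
      audit <- rbind(audit, data.frame(
        step = i, key = st$key, cell_id = as.character(rem),
        stringsAsFactors = FALSE))
    attr(out, "removed") <- NULL
  }
  list(metrics = out, audit = audit)
}
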