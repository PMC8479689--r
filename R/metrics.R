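#' Percent difference in radius or area relative to the trapped state
#'
#' The deformation measures used to compare cell states:
#' `%DR = 100 (R - RT) / R` and `%DA = 100 (A - AT) / A`, where `R`/`A` is
#' the reference (free or stretched) radius/area and `RT`/`AT` the trapped
#' one. Values are signed: positive when the trapped cell is smaller than
#' the reference.
#'
#' @param reference_radius,reference_area Reference (free or stretched)
#'   radius in um / area in um^2; must be > 0. Vectorised.
#' @param trapped_radius,trapped_area Trapped-state radius / area.
#' @return Signed percent difference(s).
#' @export
percent_diff_radius <- function(reference_radius, trapped_radius) {
  if (any(reference_radius == 0, na.rm = TRUE))
    stop("reference radius must be nonzero", call. = FALSE)
  100 * (reference_radius - trapped_radius) / reference_radius
}

#' @rdname percent_diff_radius
#' @export
percent_diff_area <- function(reference_area, trapped_area) {
  if (any(reference_area == 0, na.rm = TRUE))
    stop("reference area must be nonzero", call. = FALSE)
  100 * (reference_area - trapped_area) / reference_area
}

#' Cell stiffness from the trapped-to-stretched transition
#'
#' Stiffness `k = dF / dR` with `dR` the longitudinal radius change from the
#' trapped to the stretched state and `dF` the change in stretching force.
#' With forces in pN and radii in um the ratio is in uN/m directly.
#'
#' @param drag_force_pN,trap_force_pN Drag and trap forces, pN.
#' @param stretched_r_um,trapped_r_um Longitudinal (r_max) radii, um.
#' @param force `"net"` (default): `dF = drag - trap`, the force change from
#'   the trapped equilibrium to the dragged state; `"drag"`: `dF = drag`
#'   alone.
#' @return Stiffness in uN/m. Errors if `dR = 0` or the stretched radius is
#'   missing.
#' @export
stiffness <- function(drag_force_pN, trap_force_pN,
                      stretched_r_um, trapped_r_um,
                      force = c("net", "drag")) {
  force <- match.arg(force)
  if (any(is.na(stretched_r_um)))
    stop("incomplete record: stretched measurement missing", call. = FALSE)
  dr <- stretched_r_um - trapped_r_um
  if (any(dr == 0))
    stop("undefined stiffness: stretched and trapped radii are equal",
         call. = FALSE)
  df <- if (force == "net") drag_force_pN - trap_force_pN else drag_force_pN
  df / dr
}

#' Axis ratio of a cell outline
#'
#' Ratio of the maximum (longitudinal) over the minimum (transverse)
#' radius; 1 for a circle, larger for elongated cells.
#'
#' @param r_max A [geometry_measurement()], or the numeric r_max (um).
#' @param r_min Numeric r_min (um), required when `r_max` is numeric.
#' @return Dimensionless ratio >= 1 for valid measurements.
#' @export
axis_ratio <- function(r_max, r_min = NULL) {
  if (inherits(r_max, "geometry_measurement")) {
    r_min <- r_max$r_min
    r_max <- r_max$r_max
  }
  if (any(r_min == 0, na.rm = TRUE))
    stop("`r_min` must be nonzero", call. = FALSE)
  r_max / r_min
}

state_cols <- function(state) {
  paste0(state, c("_rmax_um", "_rmin_um", "_area_um2"))
}

record_columns <- function() {
  c("cell_id", "cohort", "subgroup", "stage_speed_um_s",
    "trap_force_pN", "drag_force_pN",
    state_cols("free"), state_cols("trapped"), state_cols("stretched"))
}

validate_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a nonempty data frame", call. = FALSE)
  missing <- setdiff(record_columns(), names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

#' Per-cell elasticity metrics
#'
#' Evaluates the full set of elasticity quantities for every cell record:
#' signed percent differences in radius and area (free vs trapped and
#' stretched vs trapped), stiffness, the stretched-minus-trapped radius
#' change, and the axis ratios of all three states. Records without a
#' stretched measurement (morphology-only) get `NA` for the
#' stretched-state metrics, not an error.
#'
#' @param records Cell-record data frame (see [read_records()] for the
#'   column schema).
#' @param stiffness_force Passed to [stiffness()]: `"net"` or `"drag"`.
#' @param radius Which radius enters the percent differences and the
#'   stiffness denominator: `"r_max"` (longitudinal; the stretch acts along
#'   this axis) or `"r_equiv"`.
#' @return A data frame with one row per cell: identifiers, forces, free
#'   radius, `pct_dr_free`, `pct_dr_stretch`, `pct_da_free`,
#'   `pct_da_stretch`, `delta_radius_um`, `stiffness_uN_m`, and
#'   `axis_ratio_free`/`_trapped`/`_stretched`.
#' @export
cell_metrics <- function(records, stiffness_force = c("net", "drag"),
                         radius = c("r_max", "r_equiv")) {
  validate_records(records)
  stiffness_force <- match.arg(stiffness_force)
  radius <- match.arg(radius)
  r_of <- function(state) {
    if (radius == "r_max") records[[paste0(state, "_rmax_um")]]
    else sqrt(records[[paste0(state, "_area_um2")]] / pi)
  }
  a_of <- function(state) records[[paste0(state, "_area_um2")]]
  rf <- r_of("free"); rt <- r_of("trapped"); rs <- r_of("stretched")
  af <- a_of("free"); at <- a_of("trapped"); as_ <- a_of("stretched")
  dr <- rs - rt
  df <- if (stiffness_force == "net")
    records$drag_force_pN - records$trap_force_pN else records$drag_force_pN
  k <- ifelse(!is.na(dr) & dr != 0, df / dr, NA_real_)
  bad <- !is.na(dr) & dr == 0
  if (any(bad))
    stop("undefined stiffness (stretched radius equals trapped) for cell(s): ",
         paste(records$cell_id[bad], collapse = ", "), call. = FALSE)
  data.frame(
    cell_id = records$cell_id,
    cohort = records$cohort,
    subgroup = records$subgroup,
    trap_force_pN = records$trap_force_pN,
    drag_force_pN = records$drag_force_pN,
    free_rmax_um = records$free_rmax_um,
    pct_dr_free = percent_diff_radius(rf, rt),
    pct_dr_stretch = ifelse(is.na(rs), NA_real_,
                            percent_diff_radius(rs, rt)),
    pct_da_free = percent_diff_area(af, at),
    pct_da_stretch = ifelse(is.na(as_), NA_real_,
                            percent_diff_area(as_, at)),
    delta_radius_um = dr,
    stiffness_uN_m = k,
    axis_ratio_free = axis_ratio(records$free_rmax_um, records$free_rmin_um),
    axis_ratio_trapped = axis_ratio(records$trapped_rmax_um,
                                    records$trapped_rmin_um),
    axis_ratio_stretched = axis_ratio(records$stretched_rmax_um,
                                      records$stretched_rmin_um),
    stringsAsFactors = FALSE)
}
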