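#' Fluid configuration for stage-motion drag
#'
#' Parameters of the viscous drag exerted on a trapped cell when the sample
#' stage moves at constant speed: the dynamic viscosity of the suspending
#' medium and a dimensionless shape factor multiplying the Stokes sphere
#' drag to absorb disc geometry and wall-proximity corrections.
#'
#' @param viscosity Dynamic viscosity, Pa s (> 0). Default is water at
#'   room temperature.
#' @param shape_factor Dimensionless multiplier on the Stokes drag (> 0).
#' @return An object of class `"fluid_config"`.
#' @export
fluid_config <- function(viscosity = 1.0e-3, shape_factor = 1.0) {
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0)
    stop("`viscosity` must be a single positive number", call. = FALSE)
  if (!is.numeric(shape_factor) || length(shape_factor) != 1L ||
      !is.finite(shape_factor) || shape_factor <= 0)
    stop("`shape_factor` must be a single positive number", call. = FALSE)
  structure(list(viscosity = viscosity, shape_factor = shape_factor),
            class = "fluid_config")
}

#' Stage-motion drag force on a trapped cell
#'
#' Stokes drag with a shape factor:
#' `F = shape_factor * 6 pi * viscosity * cell_radius * speed`.
#' At the steady displacement reached during dragging, this force balances
#' the optical trapping force, which is how the trap is calibrated.
#'
#' @param fluid A [fluid_config()].
#' @param cell_radius Cell radius in metres (> 0); vectorised.
#' @param speed Stage speed in m/s (>= 0); vectorised.
#' @return Drag force in newtons; linear in both `cell_radius` and `speed`.
#' @examples
#' drag_force(fluid_config(), 4.67e-6, 45e-6)  # ~3.96e-12 N
#' @export
drag_force <- function(fluid, cell_radius, speed) {
  stopifnot(inherits(fluid, "fluid_config"))
  if (!is.numeric(cell_radius) || any(!is.finite(cell_radius)) ||
      any(cell_radius <= 0))
    stop("`cell_radius` must be positive and finite", call. = FALSE)
  if (!is.numeric(speed) || any(!is.finite(speed)) || any(speed < 0))
    stop("`speed` must be finite and >= 0", call. = FALSE)
  fluid$shape_factor * 6 * pi * fluid$viscosity * cell_radius * speed
}

#' Calibrate the drag shape factor from target forces
#'
#' Least-squares fit of the single scalar `shape_factor` so that the Stokes
#' drag at the given speeds reproduces a set of target forces, e.g. the
#' per-subgroup mean drag forces of a stretching experiment.
#'
#' @param target_forces Target drag forces, newtons (same length as
#'   `speeds`, nonempty).
#' @param speeds Stage speeds, m/s (> 0).
#' @param fluid A [fluid_config()]; its `shape_factor` is ignored.
#' @param cell_radius Cell radius used in the drag model, metres.
#' @return A list with `shape_factor` (the fitted scalar) and `residuals`
#'   (`target_forces - fitted`).
#' @export
calibrate_shape_factor <- function(target_forces, speeds, fluid, cell_radius) {
  stopifnot(inherits(fluid, "fluid_config"))
  if (length(target_forces) == 0L || length(target_forces) != length(speeds))
    stop("`target_forces` and `speeds` must be equal-length and nonempty",
         call. = FALSE)
  if (any(!is.finite(speeds)) || any(speeds < 0))
    stop("`speeds` must be finite and >= 0", call. = FALSE)
  base <- 6 * pi * fluid$viscosity * cell_radius * speeds
  if (all(base == 0))
    stop("degenerate fit: all speeds are zero", call. = FALSE)
  k <- sum(target_forces * base) / sum(base^2)
  list(shape_factor = k, residuals = target_forces - k * base)
}
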