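#' Optical trap configuration
#'
#' Bundles the laser and medium parameters that enter the cylindrical-dipole
#' trapping-force model: a linearly polarised Gaussian beam of power `power`
#' focused to a waist `beam_waist`, trapping a cell whose refractive index is
#' `index_ratio` times that of the suspending medium (`n_medium`).
#'
#' All quantities are SI. The defaults for `n_medium` (aqueous serum) and
#' `index_ratio` (RBC relative to medium) are conventional literature values,
#' not measured constants, and should be overridden when known.
#'
#' @param power Laser power delivered at the trap, in watts. Must be > 0.
#' @param beam_waist Minimum spot radius of the focused Gaussian beam
#'   (the beam waist w0), in metres. Must be > 0.
#' @param n_medium Refractive index of the suspending medium (>= 1).
#' @param index_ratio Ratio of cell to medium refractive index, m. The trap
#'   force vanishes identically at `index_ratio = 1` (index matched).
#' @param wavelength Laser wavelength in metres; metadata only, it does not
#'   enter the force formulas.
#' @param light_speed Speed of light in vacuum, m/s.
#' @return An object of class `"optical_config"`.
#' @examples
#' cfg <- optical_config(power = 30e-3, beam_waist = 3e-6)
#' @seealso [trap_force_exact()], [beam_intensity()]
#' @export
optical_config <- function(power = 30e-3, beam_waist = 3e-6,
                           n_medium = 1.334, index_ratio = 1.05,
                           wavelength = 1064e-9,
                           light_speed = 2.99792458e8) {
  for (nm in c("power", "beam_waist", "n_medium", "index_ratio",
               "wavelength", "light_speed")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (power <= 0) stop("`power` must be > 0", call. = FALSE)
  if (beam_waist <= 0) stop("`beam_waist` must be > 0", call. = FALSE)
  if (n_medium < 1) stop("`n_medium` must be >= 1", call. = FALSE)
  if (index_ratio <= 0) stop("`index_ratio` must be > 0", call. = FALSE)
  if (light_speed <= 0) stop("`light_speed` must be > 0", call. = FALSE)
  structure(list(power = power, beam_waist = beam_waist,
                 n_medium = n_medium, index_ratio = index_ratio,
                 wavelength = wavelength, light_speed = light_speed),
            class = "optical_config")
}

#' Per-cell optical geometry
#'
#' The cell is modelled as a thin cylinder (radius much larger than
#' thickness) lying with its flat face parallel to the beam axis, displaced
#' by `trap_offset` from the trap centre along the polarisation axis.
#'
#' @param radius Cell radius rho, metres (> 0).
#' @param thickness Cylinder thickness t, metres (0 < thickness < radius).
#' @param trap_offset Displacement of the cell centre of mass from the trap
#'   centre, metres (>= 0).
#' @return An object of class `"cell_geometry"`.
#' @export
cell_geometry <- function(radius, thickness = radius / 5, trap_offset = 0) {
  for (nm in c("radius", "thickness", "trap_offset")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  if (thickness <= 0 || thickness >= radius)
    stop("`thickness` must satisfy 0 < thickness < radius", call. = FALSE)
  if (trap_offset < 0) stop("`trap_offset` must be >= 0", call. = FALSE)
  structure(list(radius = radius, thickness = thickness,
                 trap_offset = trap_offset),
            class = "cell_geometry")
}

# Index-contrast factor (m^2 - 1)/(m^2 + 1); zero when index matched.
index_contrast <- function(m) (m^2 - 1) / (m^2 + 1)

# Dimensionless small-offset parameter 4 rt rho / w0^2 that controls the
# Bessel correction and the validity of the approximate force.
offset_parameter <- function(cfg, geom) {
  4 * geom$trap_offset * geom$radius / cfg$beam_waist^2
}

force_result <- function(magnitude, direction_sign, method, a) {
  structure(list(magnitude = magnitude, direction_sign = direction_sign,
                 method = method, small_offset_parameter = a),
            class = "trap_force")
}

#' @export
print.trap_force <- function(x, ...) {
  cat(sprintf("Trap force (%s): %.4g pN, sign %+d, offset parameter %.4g\n",
              x$method, x$magnitude * 1e12, x$direction_sign,
              x$small_offset_parameter))
  invisible(x)
}

#' Gaussian beam intensity on the cell rim
#'
#' Intensity of the focused Gaussian beam at a point on the curved wall of
#' the cylindrical cell, parameterised by the azimuthal angle `phi` measured
#' from the polarisation axis:
#' \deqn{I(\phi) = \frac{2 P}{\pi w_0^2}
#'   \exp\!\left[-\frac{2\left((r_t + \rho\cos\phi)^2 +
#'   \rho^2\sin^2\phi\right)}{w_0^2}\right].}
#' When the cell is displaced (`trap_offset > 0`) the intensity is maximal at
#' `phi = pi`, the rim point nearest the beam axis.
#'
#' @param cfg An [optical_config()].
#' @param geom A [cell_geometry()].
#' @param phi Azimuthal angle(s) in radians; vectorised.
#' @return Intensity in W/m^2, same length as `phi`.
#' @export
beam_intensity <- function(cfg, geom, phi) {
  stopifnot(inherits(cfg, "optical_config"), inherits(geom, "cell_geometry"))
  if (!is.numeric(phi) || any(!is.finite(phi)))
    stop("`phi` must be finite numeric", call. = FALSE)
  w2 <- cfg$beam_waist^2
  r2 <- (geom$trap_offset + geom$radius * cos(phi))^2 +
    (geom$radius * sin(phi))^2
  2 * cfg$power / (pi * w2) * exp(-2 * r2 / w2)
}

#' Trapping force, small-offset approximation
#'
#' Closed-form magnitude of the transverse trapping force on the cylindrical
#' cell in the limit of small offset parameter \eqn{4 r_t \rho / w_0^2}:
#' \deqn{|F| = \frac{16\, n_1 P \rho^2}{c\, w_0^2}
#'   \left|\frac{m^2-1}{m^2+1}\right|
#'   \exp\!\left[-\frac{2(\rho^2 + r_t^2)}{w_0^2}\right].}
#' A warning is emitted when the offset parameter exceeds 0.1, outside the
#' regime where dropping the Bessel correction is justified.
#'
#' @inheritParams beam_intensity
#' @return A `"trap_force"` object: `magnitude` (newtons, >= 0),
#'   `direction_sign` (-1 restoring toward the trap centre when the cell is
#'   optically denser than the medium), `method`, and the recorded
#'   `small_offset_parameter`.
#' @seealso [trap_force_exact()] for the Bessel-corrected form,
#'   [trap_force_numeric()] for the quadrature evaluation.
#' @export
trap_force_small_offset <- function(cfg, geom) {
  stopifnot(inherits(cfg, "optical_config"), inherits(geom, "cell_geometry"))
  a <- offset_parameter(cfg, geom)
  if (a > 0.1)
    warning(sprintf(
      "small-offset parameter %.3g exceeds 0.1; approximation regime violated",
      a), call. = FALSE)
  force_result(small_offset_magnitude(cfg, geom),
               direction_sign(cfg$index_ratio), "small_offset", a)
}

small_offset_magnitude <- function(cfg, geom) {
  w2 <- cfg$beam_waist^2
  16 * cfg$n_medium * cfg$power * geom$radius^2 /
    (cfg$light_speed * w2) *
    abs(index_contrast(cfg$index_ratio)) *
    exp(-2 * (geom$radius^2 + geom$trap_offset^2) / w2)
}

direction_sign <- function(m) {
  if (m > 1) -1L else if (m < 1) 1L else 0L
}

#' Trapping force, closed form with Bessel correction
#'
#' The full closed-form magnitude: the small-offset expression multiplied by
#' the angular correction factor \eqn{I_0(4 r_t \rho / w_0^2)}, the modified
#' Bessel function of the first kind, order zero, which arises from the
#' azimuthal integral of the Gaussian intensity over the cylinder wall and
#' reduces to 1 at zero offset. At `trap_offset = 0` this equals
#' [trap_force_small_offset()] exactly.
#'
#' @inheritParams beam_intensity
#' @return A `"trap_force"` object (see [trap_force_small_offset()]).
#' @export
trap_force_exact <- function(cfg, geom) {
  stopifnot(inherits(cfg, "optical_config"), inherits(geom, "cell_geometry"))
  a <- offset_parameter(cfg, geom)
  # besselI overflows to Inf near argument ~709 in double precision
  if (a > 700)
    stop(sprintf(
      "Bessel correction overflows at offset parameter %.6g (limit 700)", a),
      call. = FALSE)
  force_result(small_offset_magnitude(cfg, geom) * besselI(a, 0),
               direction_sign(cfg$index_ratio), "bessel", a)
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch.
gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1L, ]^2)
}

#' Trapping force by numerical surface quadrature
#'
#' Independent evaluation of the polarisation-direction trapping force by
#' two-dimensional quadrature of the Gaussian intensity over the curved
#' cylinder wall (trapezoid rule in the periodic azimuth, Gauss-Legendre
#' across the thickness), with the same prefactor convention as
#' [trap_force_exact()]. The azimuthal resolution is doubled until the result
#' changes by less than 1e-6 relative (cap 4096 nodes); this routine serves
#' as the oracle for the closed forms.
#'
#' @inheritParams beam_intensity
#' @param n_phi Initial number of azimuthal nodes (>= 16).
#' @param n_y Number of Gauss-Legendre nodes across the thickness (>= 2).
#' @return A `"trap_force"` object with `method = "numeric"`.
#' @export
trap_force_numeric <- function(cfg, geom, n_phi = 64L, n_y = 4L) {
  stopifnot(inherits(cfg, "optical_config"), inherits(geom, "cell_geometry"))
  if (n_phi < 16L) stop("`n_phi` must be >= 16", call. = FALSE)
  if (n_y < 2L) stop("`n_y` must be >= 2", call. = FALSE)
  a <- offset_parameter(cfg, geom)
  chi <- index_contrast(cfg$index_ratio)
  if (chi == 0) return(force_result(0, 0L, "numeric", a))
  t <- geom$thickness
  gl <- gauss_legendre(as.integer(n_y))          # y in [-t/2, t/2]
  wy <- gl$w * t / 2                             # intensity is y-independent
  # prefactor 4 n1 rho / (c t) x |contrast|, applied to the surface integral
  # of I over the wall (area element rho dphi dy)
  pref <- 4 * cfg$n_medium * geom$radius /
    (cfg$light_speed * t) * abs(chi)
  surf <- function(np) {
    phi <- 2 * pi * (seq_len(np) - 1L) / np
    ii <- beam_intensity(cfg, geom, phi)
    azi <- sum(ii) * (2 * pi / np)               # periodic trapezoid
    azi * geom$radius * sum(wy)
  }
  np <- as.integer(n_phi)
  val <- surf(np)
  repeat {
    np2 <- np * 2L
    val2 <- surf(np2)
    if (abs(val2 - val) <= 1e-6 * max(abs(val2), .Machine$double.xmin)) {
      val <- val2
      break
    }
    if (np2 >= 4096L)
      stop("quadrature failed to converge at 4096 azimuthal nodes",
           call. = FALSE)
    np <- np2
    val <- val2
  }
  force_result(pref * val, direction_sign(cfg$index_ratio), "numeric", a)
}

#' Trap force versus offset profile
#'
#' Vectorised [trap_force_exact()] over a set of trap offsets, e.g. to map
#' the restoring-force profile of a trap for a given cell.
#'
#' @inheritParams beam_intensity
#' @param offsets Numeric vector of trap offsets in metres (finite, >= 0);
#'   may be empty.
#' @return A data frame with one row per offset: `offset_m`, `magnitude_N`,
#'   `direction_sign`, `small_offset_parameter`.
#' @export
force_offset_profile <- function(cfg, geom, offsets) {
  stopifnot(inherits(cfg, "optical_config"), inherits(geom, "cell_geometry"))
  if (length(offsets) == 0L)
    return(data.frame(offset_m = numeric(0), magnitude_N = numeric(0),
                      direction_sign = integer(0),
                      small_offset_parameter = numeric(0)))
  if (!is.numeric(offsets) || any(!is.finite(offsets)) || any(offsets < 0))
    stop("`offsets` must be finite and >= 0", call. = FALSE)
  res <- lapply(seq_along(offsets), function(i) {
    g <- cell_geometry(geom$radius, geom$thickness, offsets[i])
    tryCatch(trap_force_exact(cfg, g), error = function(e) {
      stop(sprintf("offset %d (%.3g m): %s", i, offsets[i],
                   conditionMessage(e)), call. = FALSE)
    })
  })
  data.frame(
    offset_m = offsets,
    magnitude_N = vapply(res, `[[`, numeric(1), "magnitude"),
    direction_sign = vapply(res, `[[`, integer(1), "direction_sign"),
    small_offset_parameter =
      vapply(res, `[[`, numeric(1), "small_offset_parameter"))
}
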