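# Run expr with a private, restored RNG stream seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

#' Grayscale cell image
#'
#' A 2-D grid of intensities with its physical pixel size. Used both for
#' synthetic renders and for images read from disk.
#'
#' @param pixels Numeric matrix of finite intensities (rows = image y,
#'   columns = image x).
#' @param pixel_size Micrometres per pixel (> 0).
#' @return An object of class `"cell_image"`.
#' @export
cell_image <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a nonempty numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("`pixels` must be finite", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "cell_image")
}

#' Geometry of a segmented cell
#'
#' Summary geometry of a cell outline: the longitudinal (maximum) and
#' transverse (minimum) semi-axes, the equivalent circular radius
#' `sqrt(area/pi)`, the area, and the major-axis orientation.
#'
#' @param r_max Longitudinal semi-axis, micrometres (`r_max >= r_min`).
#' @param r_min Transverse semi-axis, micrometres (> 0).
#' @param area Area, square micrometres (> 0).
#' @param orientation Major-axis angle, radians (defined modulo pi).
#' @return An object of class `"geometry_measurement"` with fields `r_max`,
#'   `r_min`, `r_equiv`, `area`, `orientation`.
#' @export
geometry_measurement <- function(r_max, r_min, area, orientation = 0) {
  vals <- c(r_max = r_max, r_min = r_min, area = area,
            orientation = orientation)
  if (any(!is.finite(vals)))
    stop("geometry fields must be finite", call. = FALSE)
  if (r_min <= 0 || r_max < r_min)
    stop("need r_max >= r_min > 0", call. = FALSE)
  if (area <= 0) stop("`area` must be > 0", call. = FALSE)
  structure(list(r_max = r_max, r_min = r_min,
                 r_equiv = sqrt(area / pi), area = area,
                 orientation = orientation),
            class = "geometry_measurement")
}

#' @export
print.geometry_measurement <- function(x, ...) {
  cat(sprintf(
    "Cell geometry: r_max %.3f um, r_min %.3f um, r_equiv %.3f um, area %.2f um^2\n",
    x$r_max, x$r_min, x$r_equiv, x$area))
  invisible(x)
}

#' Render a synthetic cell image
#'
#' Draws an elliptical cell of uniform foreground intensity on a uniform
#' background, with a one-pixel anti-aliasing ramp at the edge and additive
#' Gaussian pixel noise. Deterministic for a given `seed`. The render stands
#' in for a bright-field/phase micrograph of a single RBC so the
#' segmentation and morphometry stages can be exercised without microscope
#' data; it does not emulate the biconcave 3-D profile of a real cell.
#'
#' @param semi_major,semi_minor Ellipse semi-axes, micrometres.
#' @param orientation Major-axis angle, radians.
#' @param center Cell centre in pixels, length-2 (x, y); default image
#'   centre.
#' @param pixel_size Micrometres per pixel.
#' @param image_size Image side length(s) in pixels; scalar or (ncol, nrow).
#' @param fg,bg Foreground and background intensities.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   intensity units.
#' @param seed Integer RNG seed for the noise.
#' @return A [cell_image()].
#' @export
render_cell <- function(semi_major, semi_minor, orientation = 0,
                        center = NULL, pixel_size = 0.05, image_size = 256L,
                        fg = 1, bg = 0, noise_sd = 0, seed = 1L) {
  if (semi_minor > semi_major) stop("need semi_major >= semi_minor",
                                    call. = FALSE)
  a <- semi_major / pixel_size
  b <- semi_minor / pixel_size
  if (b < 2) stop("semi-axes must be >= 2 px at this pixel size",
                  call. = FALSE)
  image_size <- as.integer(rep_len(image_size, 2L))
  nc <- image_size[1L]; nr <- image_size[2L]
  if (is.null(center)) center <- c((nc + 1) / 2, (nr + 1) / 2)
  # extent check: cell (plus ramp) must sit fully inside the frame
  ext <- a + 1
  if (center[1L] - ext < 1 || center[1L] + ext > nc ||
      center[2L] - ext < 1 || center[2L] + ext > nr)
    stop("cell does not fit inside the image frame", call. = FALSE)
  xs <- seq_len(nc) - center[1L]
  ys <- seq_len(nr) - center[2L]
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  xr <- X * cos(orientation) + Y * sin(orientation)
  yr <- -X * sin(orientation) + Y * cos(orientation)
  q <- sqrt((xr / a)^2 + (yr / b)^2)
  # signed distance (px) to the ellipse boundary, first order: (q-1)/|grad q|
  gq <- sqrt((xr / a^2)^2 + (yr / b^2)^2) / pmax(q, 1e-12)
  d <- (q - 1) / pmax(gq, 1e-12)
  cov <- pmin(pmax(0.5 - d, 0), 1)
  pix <- bg + (fg - bg) * cov
  if (noise_sd > 0)
    pix <- pix + with_seed(seed, matrix(stats::rnorm(nr * nc, 0, noise_sd),
                                        nr, nc))
  cell_image(pix, pixel_size)
}

#' Segment the cell from a grayscale image
#'
#' Global threshold by between-class variance maximisation (Otsu), keeping
#' the largest connected foreground component with holes filled. The cell is
#' assumed brighter than the background.
#'
#' @param image A [cell_image()].
#' @return A logical matrix mask (TRUE = cell) with the image's
#'   `pixel_size` attached as an attribute.
#' @export
segment_cell <- function(image) {
  stopifnot(inherits(image, "cell_image"))
  pix <- image$pixels
  rng <- range(pix)
  if (diff(rng) <= 0)
    stop("segmentation failure: image has no contrast", call. = FALSE)
  norm <- (pix - rng[1L]) / diff(rng)
  th <- EBImage::otsu(norm, range = c(0, 1))
  mask <- norm > th
  if (!any(mask))
    stop("segmentation failure: no foreground above threshold",
         call. = FALSE)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask) > 0
  structure(mask, pixel_size = image$pixel_size)
}

#' Measure cell geometry from a binary mask
#'
#' Area from the pixel count; semi-axes of the equivalent ellipse from the
#' second central moments of the mask (semi-axis = 2 sqrt(eigenvalue) of the
#' pixel covariance, with a 1/12 px^2 term for the pixels' own extent);
#' orientation from the principal axis.
#'
#' @param mask Logical (or 0/1) matrix; nonempty.
#' @param pixel_size Micrometres per pixel; defaults to the mask's
#'   `pixel_size` attribute when present.
#' @return A [geometry_measurement()].
#' @export
measure_geometry <- function(mask, pixel_size = attr(mask, "pixel_size")) {
  if (is.null(pixel_size))
    stop("`pixel_size` is required", call. = FALSE)
  m <- mask > 0
  n <- sum(m)
  if (n == 0L) stop("mask is empty", call. = FALSE)
  idx <- which(m, arr.ind = TRUE)
  x <- idx[, 2L]; y <- idx[, 1L]
  mx <- mean(x); my <- mean(y)
  m20 <- mean((x - mx)^2) + 1 / 12
  m02 <- mean((y - my)^2) + 1 / 12
  m11 <- mean((x - mx) * (y - my))
  tr <- m20 + m02
  det_ <- m20 * m02 - m11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  geometry_measurement(
    r_max = 2 * sqrt(l1) * pixel_size,
    r_min = 2 * sqrt(max(l2, 1e-12)) * pixel_size,
    area = n * pixel_size^2,
    orientation = 0.5 * atan2(2 * m11, m20 - m02))
}

#' Read or write a grayscale cell image as PNG
#'
#' Intensities are clipped to \[0, 1\] on write; the pixel size is not
#' stored in the file and must be supplied on read.
#'
#' @param image A [cell_image()].
#' @param path File path.
#' @param pixel_size Micrometres per pixel of the stored image.
#' @return `read_cell_image` returns a [cell_image()];
#'   `write_cell_image` returns `path` invisibly.
#' @export
write_cell_image <- function(image, path) {
  stopifnot(inherits(image, "cell_image"))
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for image I/O", call. = FALSE)
  png::writePNG(pmin(1, pmax(0, image$pixels)), path)
  invisible(path)
}

#' @rdname write_cell_image
#' @export
read_cell_image <- function(path, pixel_size) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for image I/O", call. = FALSE)
  pix <- png::readPNG(path)
  if (length(dim(pix)) == 3L) pix <- pix[, , 1L]
  cell_image(pix, pixel_size)
}
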