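# Truncated-normal draws by rejection; sd = 0 collapses to the mean.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate truncated normal: mean outside bounds", call. = FALSE)
    return(rep(mean, n))
  }
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L)
      stop("truncated-normal rejection failed to terminate", call. = FALSE)
  }
  x
}

# Published seven-subgroup mean drag-force profile (pN); the generator
# rescales it so its mean equals the cohort drag-force target.
subgroup_drag_profile <- c(1.48, 1.26, 1.10, 0.853, 0.635, 4.31, 3.23)

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic-cohort generator. Two modes mirror the two
#' measurement campaigns of the underlying experiment: a `morphology`
#' survey (free-cell diameters only, optionally rendered to images) and an
#' `elasticity` experiment (free/trapped/stretched states with forces, the
#' cohort split into seven equal stage-speed subgroups).
#'
#' Dispersion parameters without published values (force and stiffness
#' coefficients of variation, trap-compression percentages, axis-ratio
#' spread, measurement noise) carry package defaults chosen as plausible
#' for RBC optical-stretching data; they are not measured constants.
#'
#' @param label Cohort label, e.g. `"HbAS"`, `"HbSS"`, `"SCT"`, `"SCA"`.
#' @param mode `"morphology"` or `"elasticity"`.
#' @param n_cells Number of cells; in elasticity mode must be divisible
#'   by 7 (the subgroup count).
#' @param diameter_mean,diameter_sd Free-cell diameter distribution, um
#'   (morphology mode).
#' @param radius_mean Mean free longitudinal radius, um (elasticity mode).
#' @param radius_range Length-2 truncation range for the free radius, um.
#' @param radius_sd Spread of the free-radius truncated normal, um;
#'   defaults to a quarter of the range width.
#' @param axis_ratio_mean,axis_ratio_sd Free-cell axis-ratio distribution
#'   (clipped at >= 1).
#' @param trap_compression_mean,trap_compression_sd Percent radius
#'   reduction from free to trapped state.
#' @param trap_force_mean Mean trap force, pN; `trap_force_cv` its
#'   coefficient of variation.
#' @param drag_force_mean Cohort mean drag force target, pN; subgroup stage
#'   speeds are back-solved from the rescaled subgroup drag profile unless
#'   `subgroup_speeds` is given.
#' @param subgroup_speeds Optional seven stage speeds, um/s.
#' @param stiffness_mean Mean cell stiffness, uN/m; `stiffness_cv` its
#'   coefficient of variation.
#' @param fluid A [fluid_config()] used to back-solve speeds and compute
#'   per-cell drag forces.
#' @param noise Measurement-noise standard deviation as a fraction of the
#'   recorded value.
#' @param noise_model `"scale"`: one multiplier per cell shared by every
#'   geometry value (per-cell magnification/calibration error);
#'   `"independent"`: an independent multiplier per recorded state.
#' @param seed Default RNG seed for generators run without an explicit
#'   seed.
#' @return An object of class `"cohort_config"`.
#' @seealso [default_cohort_configs()] for the published-cohort presets.
#' @export
cohort_config <- function(label, mode = c("elasticity", "morphology"),
                          n_cells = 49L,
                          diameter_mean = NULL, diameter_sd = NULL,
                          radius_mean = NULL, radius_range = NULL,
                          radius_sd = NULL,
                          axis_ratio_mean = 1.05, axis_ratio_sd = 0.03,
                          trap_compression_mean = 10,
                          trap_compression_sd = 2.5,
                          trap_force_mean = NULL, trap_force_cv = 0.25,
                          drag_force_mean = NULL, subgroup_speeds = NULL,
                          stiffness_mean = NULL, stiffness_cv = 0.25,
                          fluid = fluid_config(), noise = 0.01,
                          noise_model = c("scale", "independent"),
                          seed = 1L) {
  mode <- match.arg(mode)
  noise_model <- match.arg(noise_model)
  n_cells <- as.integer(n_cells)
  problems <- character(0)
  need_pos <- function(x, nm) {
    if (is.null(x) || !is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
      problems <<- c(problems, nm)
  }
  if (n_cells < 1L) problems <- c(problems, "n_cells")
  if (mode == "morphology") {
    need_pos(diameter_mean, "diameter_mean")
    if (is.null(diameter_sd) || diameter_sd < 0)
      problems <- c(problems, "diameter_sd")
  } else {
    need_pos(radius_mean, "radius_mean")
    need_pos(trap_force_mean, "trap_force_mean")
    need_pos(drag_force_mean, "drag_force_mean")
    need_pos(stiffness_mean, "stiffness_mean")
    if (is.null(radius_range) || length(radius_range) != 2L ||
        !(radius_range[1L] < radius_mean && radius_mean < radius_range[2L]))
      problems <- c(problems, "radius_range")
    if (n_cells %% 7L != 0L)
      problems <- c(problems, "n_cells (must be divisible by 7)")
    if (!is.null(subgroup_speeds) && length(subgroup_speeds) != 7L)
      problems <- c(problems, "subgroup_speeds")
  }
  if (trap_force_cv < 0 || stiffness_cv < 0) problems <- c(problems, "cv")
  if (noise < 0) problems <- c(problems, "noise")
  if (length(problems))
    stop("invalid cohort config; offending fields: ",
         paste(problems, collapse = ", "), call. = FALSE)
  if (mode == "elasticity" && is.null(radius_sd))
    radius_sd <- diff(radius_range) / 4
  structure(list(
    label = label, mode = mode, n_cells = n_cells,
    diameter_mean = diameter_mean, diameter_sd = diameter_sd,
    radius_mean = radius_mean, radius_range = radius_range,
    radius_sd = radius_sd,
    axis_ratio_mean = axis_ratio_mean, axis_ratio_sd = axis_ratio_sd,
    trap_compression_mean = trap_compression_mean,
    trap_compression_sd = trap_compression_sd,
    trap_force_mean = trap_force_mean, trap_force_cv = trap_force_cv,
    drag_force_mean = drag_force_mean, subgroup_speeds = subgroup_speeds,
    stiffness_mean = stiffness_mean, stiffness_cv = stiffness_cv,
    fluid = fluid, noise = noise, noise_model = noise_model,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Published-cohort configuration presets
#'
#' Configurations whose location parameters are the published cohort
#' statistics: the morphology survey (SCT mean diameter 4.02 um, sd 0.60;
#' SCA 6.60 um, sd 0.90) and the 49-cell elasticity cohorts (HbAS free
#' radius mean 4.67 um on 3.84-5.38, trap force 0.26 pN, drag 1.20 pN,
#' stiffness 1.08 uN/m; HbSS 5.24 um on 4.45-6.12, 0.33 pN, 1.27 pN,
#' 4.47 uN/m). Dispersion parameters without published values use package
#' defaults (documented in [cohort_config()]); the trapped-state
#' compression means (12% HbAS vs 8% HbSS) are package defaults set so the
#' trait cohort deforms more, consistent with the published comparison.
#'
#' @return A named list of [cohort_config()]s: `hbas`, `hbss` (elasticity,
#'   n = 49) and `sct`, `sca` (morphology, n = 200).
#' @export
default_cohort_configs <- function() {
  list(
    hbas = cohort_config(
      "HbAS", "elasticity", n_cells = 49L,
      radius_mean = 4.67, radius_range = c(3.84, 5.38),
      trap_force_mean = 0.26, drag_force_mean = 1.20,
      stiffness_mean = 1.08, trap_compression_mean = 12),
    hbss = cohort_config(
      "HbSS", "elasticity", n_cells = 49L,
      radius_mean = 5.24, radius_range = c(4.45, 6.12),
      trap_force_mean = 0.33, drag_force_mean = 1.27,
      stiffness_mean = 4.47, trap_compression_mean = 8),
    sct = cohort_config(
      "SCT", "morphology", n_cells = 200L,
      diameter_mean = 4.02, diameter_sd = 0.60),
    sca = cohort_config(
      "SCA", "morphology", n_cells = 200L,
      diameter_mean = 6.60, diameter_sd = 0.90))
}

#' Subgroup stage speeds for an elasticity config
#'
#' The seven stage speeds are back-solved from the subgroup drag-force
#' profile (the published seven subgroup means rescaled so their mean
#' equals the config's cohort drag-force target) through the Stokes drag at
#' the cohort mean radius.
#'
#' @param config An elasticity-mode [cohort_config()].
#' @return Seven stage speeds in um/s.
#' @export
subgroup_stage_speeds <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$mode != "elasticity")
    stop("subgroup speeds are defined for elasticity mode only",
         call. = FALSE)
  if (!is.null(config$subgroup_speeds)) return(config$subgroup_speeds)
  targets_pN <- subgroup_drag_profile *
    config$drag_force_mean / mean(subgroup_drag_profile)
  v_m_s <- targets_pN * 1e-12 /
    (config$fluid$shape_factor * 6 * pi * config$fluid$viscosity *
       config$radius_mean * 1e-6)
  v_m_s * 1e6
}

new_rbc_cohort <- function(records, latent, config, seed, images = NULL) {
  structure(list(records = records, latent = latent, config = config,
                 seed = seed, images = images), class = "rbc_cohort")
}

#' @export
print.rbc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic %s cohort `%s`: %d cells (seed %d)\n",
              x$config$mode, x$config$label, nrow(x$records), x$seed))
  if (x$config$mode == "elasticity")
    cat(sprintf("  mean free r_max %.2f um, trap %.2f pN, drag %.2f pN\n",
                mean(x$records$free_rmax_um),
                mean(x$records$trap_force_pN),
                mean(x$records$drag_force_pN)))
  else
    cat(sprintf("  mean diameter %.2f um\n",
                2 * sqrt(mean(x$records$free_area_um2 / pi))))
  invisible(x)
}

apply_measurement_noise <- function(rec, config) {
  n <- nrow(rec)
  if (config$noise == 0) return(list(records = rec, scale = rep(1, n)))
  geom_cols <- c(state_cols("free"), state_cols("trapped"),
                 state_cols("stretched"))
  if (config$noise_model == "scale") {
    eps <- 1 + stats::rnorm(n, 0, config$noise)
    for (col in geom_cols) {
      pow <- if (grepl("area", col)) 2 else 1
      rec[[col]] <- rec[[col]] * eps^pow
    }
    return(list(records = rec, scale = eps))
  }
  # independent multiplier per state; redraw a state's multiplier if it
  # breaks the trapped < stretched ordering of the longitudinal radius
  for (state in c("free", "trapped", "stretched")) {
    eps <- 1 + stats::rnorm(n, 0, config$noise)
    if (state == "stretched") {
      tr <- rec$trapped_rmax_um
      base <- rec$stretched_rmax_um
      guard <- 0L
      repeat {
        bad <- which(!is.na(base) & base * eps <= tr)
        if (!length(bad)) break
        eps[bad] <- 1 + stats::rnorm(length(bad), 0, config$noise)
        guard <- guard + 1L
        if (guard > 10000L)
          stop("could not draw order-preserving measurement noise",
               call. = FALSE)
      }
    }
    for (col in state_cols(state)) {
      pow <- if (grepl("area", col)) 2 else 1
      rec[[col]] <- rec[[col]] * eps^pow
    }
  }
  list(records = rec, scale = rep(NA_real_, n))
}

#' Generate a synthetic morphology cohort
#'
#' Draws free-cell diameters from a truncated normal (> 1 um), axis ratios
#' from a normal clipped at >= 1, derives the elliptical free geometry
#' (the equivalent radius is half the drawn diameter), applies measurement
#' noise to the recorded values, and optionally renders each cell to a
#' synthetic image via [render_cell()] for the segmentation pipeline.
#' Deterministic for a given (config, seed).
#'
#' @param config A morphology-mode [cohort_config()].
#' @param render_images If `TRUE`, a list of [cell_image()]s is attached.
#' @param seed RNG seed; defaults to the config's.
#' @param pixel_size Micrometres per pixel for rendered images.
#' @param render_noise_sd Pixel-noise standard deviation of the renders,
#'   in units of the unit foreground-background contrast.
#' @return An `"rbc_cohort"` object: `records` (the recorded measurement
#'   table), `latent` (the true per-cell values), `config`, `seed`, and
#'   optionally `images`.
#' @export
generate_morphology_cohort <- function(config, render_images = FALSE,
                                       seed = NULL, pixel_size = 0.05,
                                       render_noise_sd = 0.02) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$mode != "morphology")
    stop("config is not in morphology mode", call. = FALSE)
  if (is.null(seed)) seed <- config$seed
  n <- config$n_cells
  with_seed(seed, {
    diam <- rtnorm(n, config$diameter_mean, config$diameter_sd, lower = 1)
    ar <- rtnorm(n, config$axis_ratio_mean, config$axis_ratio_sd, lower = 1)
    orient <- stats::runif(n, 0, pi)
    img_seeds <- sample.int(.Machine$integer.max, n)
    r_equiv <- diam / 2
    r_max <- r_equiv * sqrt(ar)
    r_min <- r_equiv / sqrt(ar)
    latent <- data.frame(
      cell_id = sprintf("%s_%03d", config$label, seq_len(n)),
      diameter_um = diam, axis_ratio = ar,
      free_rmax_um = r_max, free_rmin_um = r_min,
      free_area_um2 = pi * r_max * r_min,
      orientation = orient, stringsAsFactors = FALSE)
    rec <- data.frame(
      cell_id = latent$cell_id, cohort = config$label,
      subgroup = NA_integer_, stage_speed_um_s = NA_real_,
      trap_force_pN = NA_real_, drag_force_pN = NA_real_,
      free_rmax_um = r_max, free_rmin_um = r_min,
      free_area_um2 = pi * r_max * r_min,
      trapped_rmax_um = NA_real_, trapped_rmin_um = NA_real_,
      trapped_area_um2 = NA_real_,
      stretched_rmax_um = NA_real_, stretched_rmin_um = NA_real_,
      stretched_area_um2 = NA_real_, stringsAsFactors = FALSE)
    noised <- apply_measurement_noise(rec, config)
    images <- NULL
    if (render_images) {
      images <- lapply(seq_len(n), function(i) {
        side <- 2L * as.integer(ceiling(r_max[i] / pixel_size)) + 24L
        render_cell(r_max[i], r_min[i], orientation = orient[i],
                    pixel_size = pixel_size, image_size = side,
                    noise_sd = render_noise_sd, seed = img_seeds[i])
      })
      names(images) <- latent$cell_id
    }
    new_rbc_cohort(noised$records, latent, config, seed, images)
  })
}

#' Generate a synthetic elasticity cohort
#'
#' Builds the 7-subgroup stretching experiment record by record: free
#' geometry from a truncated normal on the configured radius range; a
#' trapped state compressed by a drawn percentage; a trap force drawn about
#' the cohort mean (truncated below the cell's drag force so every record
#' is physically consistent); the drag force from Stokes drag at the cell's
#' subgroup stage speed; a latent stiffness drawn about the cohort mean;
#' and a stretched state whose longitudinal radius inverts the stiffness
#' definition, `r_stretched = r_trapped + (F_drag - F_trap)/k`. Areas are
#' elliptical in every state; measurement noise is applied to the recorded
#' (not latent) values. Deterministic for a given (config, seed).
#'
#' @param config An elasticity-mode [cohort_config()].
#' @param seed RNG seed; defaults to the config's.
#' @return An `"rbc_cohort"` object (see [generate_morphology_cohort()]);
#'   `latent` holds the true radii, forces, stiffness and compression used
#'   to build each record.
#' @export
generate_elasticity_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$mode != "elasticity")
    stop("config is not in elasticity mode", call. = FALSE)
  if (is.null(seed)) seed <- config$seed
  n <- config$n_cells
  per <- n %/% 7L
  speeds <- subgroup_stage_speeds(config)
  subgroup <- rep(seq_len(7L), each = per)
  with_seed(seed, {
    r_free <- rtnorm(n, config$radius_mean, config$radius_sd,
                     lower = config$radius_range[1L],
                     upper = config$radius_range[2L])
    ar <- rtnorm(n, config$axis_ratio_mean, config$axis_ratio_sd, lower = 1)
    comp <- rtnorm(n, config$trap_compression_mean,
                   config$trap_compression_sd, lower = 0.5, upper = 40)
    v_um_s <- speeds[subgroup]
    drag_pN <- drag_force(config$fluid, r_free * 1e-6, v_um_s * 1e-6) * 1e12
    trap_sd <- config$trap_force_cv * config$trap_force_mean
    trap_pN <- vapply(seq_len(n), function(i) {
      rtnorm(1L, config$trap_force_mean, trap_sd,
             lower = 1e-6, upper = 0.95 * drag_pN[i])
    }, numeric(1))
    k_sd <- config$stiffness_cv * config$stiffness_mean
    k <- rtnorm(n, config$stiffness_mean, k_sd,
                lower = 0.05 * config$stiffness_mean)
    free_rmin <- r_free / ar
    trap_rmax <- r_free * (1 - comp / 100)
    trap_rmin <- free_rmin * (1 - comp / 100)
    stretch_rmax <- trap_rmax + (drag_pN - trap_pN) / k  # pN/(uN/m) = um
    stretch_rmin <- trap_rmin
    if (any(stretch_rmax <= trap_rmax))
      stop("infeasible config: stretched radius not larger than trapped",
           call. = FALSE)
    latent <- data.frame(
      cell_id = sprintf("%s_%03d", config$label, seq_len(n)),
      subgroup = subgroup, stage_speed_um_s = v_um_s,
      free_rmax_um = r_free, free_rmin_um = free_rmin,
      trapped_rmax_um = trap_rmax, trapped_rmin_um = trap_rmin,
      stretched_rmax_um = stretch_rmax, stretched_rmin_um = stretch_rmin,
      trap_force_pN = trap_pN, drag_force_pN = drag_pN,
      stiffness_uN_m = k, compression_pct = comp, axis_ratio = ar,
      stringsAsFactors = FALSE)
    rec <- data.frame(
      cell_id = latent$cell_id, cohort = config$label,
      subgroup = subgroup, stage_speed_um_s = v_um_s,
      trap_force_pN = trap_pN, drag_force_pN = drag_pN,
      free_rmax_um = r_free, free_rmin_um = free_rmin,
      free_area_um2 = pi * r_free * free_rmin,
      trapped_rmax_um = trap_rmax, trapped_rmin_um = trap_rmin,
      trapped_area_um2 = pi * trap_rmax * trap_rmin,
      stretched_rmax_um = stretch_rmax, stretched_rmin_um = stretch_rmin,
      stretched_area_um2 = pi * stretch_rmax * stretch_rmin,
      stringsAsFactors = FALSE)
    noised <- apply_measurement_noise(rec, config)
    new_rbc_cohort(noised$records, latent, config, seed)
  })
}

#' Measure the rendered images of a morphology cohort
#'
#' Runs segment-and-measure over every rendered image of a cohort,
#' mirroring the interactive image-analysis step of the experiment.
#'
#' @param cohort An `"rbc_cohort"` generated with `render_images = TRUE`.
#' @return A data frame with `cell_id`, `r_max_um`, `r_min_um`,
#'   `r_equiv_um`, `area_um2`, `diameter_um` (= 2 r_equiv).
#' @export
measure_cohort_images <- function(cohort) {
  stopifnot(inherits(cohort, "rbc_cohort"))
  if (is.null(cohort$images))
    stop("cohort has no rendered images", call. = FALSE)
  rows <- lapply(names(cohort$images), function(id) {
    g <- measure_geometry(segment_cell(cohort$images[[id]]))
    data.frame(cell_id = id, r_max_um = g$r_max, r_min_um = g$r_min,
               r_equiv_um = g$r_equiv, area_um2 = g$area,
               diameter_um = 2 * g$r_equiv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
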